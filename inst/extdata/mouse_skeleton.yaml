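joint_names:
- lower_spine
- middle_spine
- upper_spine
- nose
- tail_base
- tail_tip
- left_shoulder
- left_elbow
- left_wrist
- right_shoulder
- right_elbow
- right_wrist
- left_hip
- left_knee
- left_ankle
- right_hip
- right_knee
- right_ankle
parents:
- ''
- lower_spine
- middle_spine
- upper_spine
- lower_spine
- tail_base
- upper_spine
- left_shoulder
- left_elbow
- upper_spine
- right_shoulder
- right_elbow
- lower_spine
- left_hip
- left_knee
- lower_spine
- right_hip
- right_knee
rest_direction:
  middle_spine:
  - 1.0
  - 0.0
  - 0.0
  upper_spine:
  - 1.0
  - 0.0
  - 0.0
  nose:
  - 1.0
  - 0.0
  - 0.0
  tail_base:
  - -1.0
  - 0.0
  - 0.0
  tail_tip:
  - -1.0
  - 0.0
  - 0.0
  left_shoulder:
  - 0.0
  - 0.707106781186547
  - -0.707106781186547
  left_elbow:
  - 0.0
  - 0.0
  - -1.0
  left_wrist:
  - 0.0
  - 0.0
  - -1.0
  right_shoulder:
  - 0.0
  - -0.707106781186547
  - -0.707106781186547
  right_elbow:
  - 0.0
  - 0.0
  - -1.0
  right_wrist:
  - 0.0
  - 0.0
  - -1.0
  left_hip:
  - 0.0
  - 0.707106781186547
  - -0.707106781186547
  left_knee:
  - 0.0
  - 0.0
  - -1.0
  left_ankle:
  - 0.0
  - 0.0
  - -1.0
  right_hip:
  - 0.0
  - -0.707106781186547
  - -0.707106781186547
  right_knee:
  - 0.0
  - 0.0
  - -1.0
  right_ankle:
  - 0.0
  - 0.0
  - -1.0
keypoint_names:
- lower_spine
- middle_spine
- upper_spine
- nose
- tail_base
- tail_tip
- left_shoulder
- left_elbow
- left_wrist
- right_shoulder
- right_elbow
- right_wrist
- left_hip
- left_knee
- left_ankle
- right_hip
- right_knee
- right_ankle
- left_ear
- right_ear
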