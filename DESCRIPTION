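Package: mouselift
Title: Monocular 3D Mouse Pose Reconstruction by Kinematic-Chain Optimization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs the 3D pose of a laboratory mouse from single-view
    2D keypoint detections by optimizing the joint angles and bone lengths of
    an 18-joint kinematic chain against the observed keypoints, regularized by
    Gaussian-mixture pose and shape priors and a fixed camera-distance
    constraint. Includes pinhole camera models with multiview triangulation
    for ground-truth reconstruction, object-keypoint-similarity (OKS)
    evaluation of 2D predictions, treadmill gait analysis (Fourier-peak
    aggregate stride, peak-to-peak individual strides, sigma-based outlier
    exclusion), and a synthetic-scene generator so the full pipeline is
    testable without video data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    minpack.lm,
    withr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
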