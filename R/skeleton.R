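#' Skeleton definitions and forward kinematics
#'
#' The mouse body is modeled as a kinematic tree of 18 joints connected by
#' rigid bones. Every joint is spherical (3 rotational degrees of freedom,
#' parameterized as an axis-angle rotation vector), so a full pose has
#' 18 x 3 = 54 joint angles plus 17 bone lengths and the placement of the
#' root. Two additional keypoints (the ears) are tracked in 2D but are not
#' part of the articulated chain; they are derived points on the head
#' segment.
#'
#' @name skeleton
NULL

#' Construct a skeleton definition
#'
#' @param joint_names character vector of joint identifiers; the first entry
#'   whose parent is `NA` is the root.
#' @param parent_index integer vector, same length; index of each joint's
#'   parent in `joint_names` (`NA` for the root).
#' @param rest_direction numeric matrix, one row per non-root joint (named by
#'   the child joint), each a unit vector giving the bone direction from the
#'   parent in the parent's frame at the rest pose.
#' @param keypoint_names character vector of all tracked keypoint names;
#'   must contain every joint name.
#' @return An object of class `skeleton_definition`.
#' @export
skeleton_definition <- function(joint_names, parent_index, rest_direction,
                                keypoint_names = joint_names) {
  joint_names <- as.character(joint_names)
  n <- length(joint_names)
  if (n < 1L) stop("skeleton must have at least one joint")
  if (anyDuplicated(joint_names)) stop("duplicate joint names")
  if (length(parent_index) != n) stop("parent_index length mismatch")
  root <- which(is.na(parent_index))
  if (length(root) != 1L) stop("skeleton must have exactly one root joint")
  # tree check: every joint must reach the root without cycles
  for (j in seq_len(n)) {
    seen <- logical(n); i <- j
    while (!is.na(parent_index[i])) {
      if (seen[i]) stop("parent graph contains a cycle")
      seen[i] <- TRUE
      i <- parent_index[i]
      if (i < 1L || i > n) stop("parent_index out of range")
    }
  }
  non_root <- joint_names[-root]
  rest_direction <- as.matrix(rest_direction)
  if (nrow(rest_direction) != n - 1L || ncol(rest_direction) != 3L)
    stop("rest_direction must be (n_joints - 1) x 3")
  if (is.null(rownames(rest_direction))) rownames(rest_direction) <- non_root
  rest_direction <- rest_direction[non_root, , drop = FALSE]
  nrm <- sqrt(rowSums(rest_direction^2))
  if (any(abs(nrm - 1) > 1e-9)) stop("rest directions must be unit vectors")
  keypoint_names <- as.character(keypoint_names)
  if (!all(joint_names %in% keypoint_names))
    stop("keypoint_names must include every joint name")
  structure(list(
    joint_names = joint_names,
    parent_index = as.integer(parent_index),
    root_index = root,
    rest_direction = rest_direction,
    keypoint_names = keypoint_names,
    n_joints = n
  ), class = "skeleton_definition")
}

#' The default laboratory-mouse skeleton
#'
#' An 18-joint tree rooted at the lower spine (the pelvis anchor, defined as
#' the midpoint between the hip joints): a spine chain
#' (lower/middle/upper spine, nose), a two-point tail, and four
#' three-segment limbs. The rest pose runs the spine along +x (nose forward),
#' dorsal side up (+z), with the limbs splayed 45 degrees downward at the
#' girdles and hanging vertically below. The ears are keypoints only; they
#' never articulate.
#'
#' All 3D quantities are in millimetres; angles are radians.
#'
#' @return A `skeleton_definition` with 18 joints and 20 keypoint names.
#' @examples
#' sk <- build_default_mouse_skeleton()
#' sk$n_joints      # 18
#' count_dof(sk)    # 54
#' @export
build_default_mouse_skeleton <- function() {
  j <- c("lower_spine", "middle_spine", "upper_spine", "nose",
         "tail_base", "tail_tip",
         "left_shoulder", "left_elbow", "left_wrist",
         "right_shoulder", "right_elbow", "right_wrist",
         "left_hip", "left_knee", "left_ankle",
         "right_hip", "right_knee", "right_ankle")
  parent_of <- c(lower_spine = NA, middle_spine = "lower_spine",
                 upper_spine = "middle_spine", nose = "upper_spine",
                 tail_base = "lower_spine", tail_tip = "tail_base",
                 left_shoulder = "upper_spine", left_elbow = "left_shoulder",
                 left_wrist = "left_elbow",
                 right_shoulder = "upper_spine", right_elbow = "right_shoulder",
                 right_wrist = "right_elbow",
                 left_hip = "lower_spine", left_knee = "left_hip",
                 left_ankle = "left_knee",
                 right_hip = "lower_spine", right_knee = "right_hip",
                 right_ankle = "right_knee")
  parent_index <- match(parent_of[j], j)
  s <- 1 / sqrt(2)
  rd <- rbind(
    middle_spine   = c(1, 0, 0),
    upper_spine    = c(1, 0, 0),
    nose           = c(1, 0, 0),
    tail_base      = c(-1, 0, 0),
    tail_tip       = c(-1, 0, 0),
    left_shoulder  = c(0,  s, -s),
    left_elbow     = c(0, 0, -1),
    left_wrist     = c(0, 0, -1),
    right_shoulder = c(0, -s, -s),
    right_elbow    = c(0, 0, -1),
    right_wrist    = c(0, 0, -1),
    left_hip       = c(0,  s, -s),
    left_knee      = c(0, 0, -1),
    left_ankle     = c(0, 0, -1),
    right_hip      = c(0, -s, -s),
    right_knee     = c(0, 0, -1),
    right_ankle    = c(0, 0, -1)
  )
  skeleton_definition(
    joint_names = j,
    parent_index = parent_index,
    rest_direction = rd,
    keypoint_names = c(j, "left_ear", "right_ear")
  )
}

#' Representative adult-mouse bone lengths (mm) for the default skeleton
#'
#' Segment lengths of a medium adult animal, used as the center of the
#' synthetic cohort generator. Named by the child joint of each bone, in
#' skeleton order.
#'
#' @param skeleton a `skeleton_definition`; defaults to the mouse skeleton.
#' @return Named numeric vector of 17 lengths in millimetres.
#' @export
default_bone_lengths <- function(skeleton = build_default_mouse_skeleton()) {
  base <- c(middle_spine = 15, upper_spine = 15, nose = 25,
            tail_base = 10, tail_tip = 60,
            left_shoulder = 8, left_elbow = 10, left_wrist = 10,
            right_shoulder = 8, right_elbow = 10, right_wrist = 10,
            left_hip = 7, left_knee = 12, left_ankle = 13,
            right_hip = 7, right_knee = 12, right_ankle = 13)
  nm <- skeleton$joint_names[-skeleton$root_index]
  if (!all(nm %in% names(base)))
    stop("default lengths are defined for the default mouse skeleton only")
  base[nm]
}

#' Number of rotational degrees of freedom of a skeleton
#'
#' Every joint is spherical, so the count is 3 per joint (the root triple is
#' the global body orientation).
#'
#' @param skeleton a `skeleton_definition`.
#' @return Integer, 3 x number of joints.
#' @export
count_dof <- function(skeleton) {
  stopifnot(inherits(skeleton, "skeleton_definition"))
  3L * skeleton$n_joints
}

#' Construct a pose state
#'
#' @param angles numeric vector of 3 x n_joints axis-angle components
#'   (radians); the root joint's triple is the global orientation.
#' @param bone_lengths strictly positive lengths (mm), one per non-root
#'   joint, in skeleton order (named vectors are matched by name).
#' @param root_translation 3-vector, the root joint position (mm).
#' @param skeleton the `skeleton_definition` the pose refers to.
#' @return An object of class `pose_state`.
#' @export
pose_state <- function(angles, bone_lengths, root_translation, skeleton) {
  stopifnot(inherits(skeleton, "skeleton_definition"))
  n <- skeleton$n_joints
  if (length(angles) != 3L * n)
    stop(sprintf("angles must have length %d (3 per joint), got %d",
                 3L * n, length(angles)))
  bone_names <- skeleton$joint_names[-skeleton$root_index]
  if (!is.null(names(bone_lengths))) {
    if (!all(bone_names %in% names(bone_lengths)))
      stop("bone_lengths names do not cover the skeleton's bones")
    bone_lengths <- bone_lengths[bone_names]
  } else if (length(bone_lengths) == n - 1L) {
    names(bone_lengths) <- bone_names
  } else {
    stop("bone_lengths must have one entry per non-root joint")
  }
  if (any(!is.finite(bone_lengths)) || any(bone_lengths <= 0))
    stop("bone lengths must be strictly positive and finite")
  if (length(root_translation) != 3L)
    stop("root_translation must be a 3-vector")
  structure(list(
    angles = as.numeric(angles),
    bone_lengths = bone_lengths,
    root_translation = as.numeric(root_translation)
  ), class = "pose_state")
}

#' Rest pose for a skeleton
#'
#' All joint angles zero (bones along their rest directions) at the given
#' root position.
#'
#' @inheritParams pose_state
#' @param skeleton a `skeleton_definition`.
#' @export
rest_pose <- function(skeleton, bone_lengths = default_bone_lengths(skeleton),
                      root_translation = c(0, 0, 0)) {
  pose_state(rep(0, 3L * skeleton$n_joints), bone_lengths, root_translation,
             skeleton)
}

# Lateral/vertical ear offsets in the head-segment frame, as fractions of the
# upper_spine->nose bone length. Ears never enter the optimizer residual.
.ear_frac <- list(along = 0.6, lateral = 0.35, up = 0.15)

#' Forward kinematics: 3D keypoint positions from a pose
#'
#' Maps joint angles and bone lengths to 3D joint positions, composing each
#' joint's rotation down the chain: the root sits at its translation with the
#' orientation given by its angle triple, and each non-root joint lies at
#' its parent's position plus the chain-composed rotation applied to
#' (rest direction x bone length). Ear keypoints, when present in the
#' skeleton's keypoint list, are fixed offsets in the head-segment frame.
#'
#' @param skeleton a `skeleton_definition`.
#' @param pose a `pose_state` with matching dimensions.
#' @return A `keypoints3d` object: an n_keypoints x 3 matrix (mm) with
#'   rownames, all rows valid.
#' @examples
#' sk <- build_default_mouse_skeleton()
#' kp <- forward_kinematics(sk, rest_pose(sk))
#' kp["nose", ]  # 55 mm ahead of the root
#' @export
forward_kinematics <- function(skeleton, pose) {
  stopifnot(inherits(skeleton, "skeleton_definition"),
            inherits(pose, "pose_state"))
  n <- skeleton$n_joints
  if (length(pose$angles) != 3L * n)
    stop("pose angle dimension does not match skeleton")
  if (any(pose$bone_lengths <= 0)) stop("bone lengths must be positive")
  pos <- matrix(NA_real_, n, 3L, dimnames = list(skeleton$joint_names, NULL))
  rots <- vector("list", n)
  # joints are stored parent-before-child? not guaranteed: process in
  # topological order by repeated sweeps (tree is tiny)
  order <- integer(0); done <- logical(n)
  repeat {
    ready <- which(!done & (is.na(skeleton$parent_index) |
                              done[pmax(skeleton$parent_index, 1L)]))
    if (length(ready) == 0L) break
    order <- c(order, ready); done[ready] <- TRUE
  }
  for (i in order) {
    Ri <- rotvec_to_matrix(pose$angles[(3L * (i - 1L) + 1L):(3L * i)])
    p <- skeleton$parent_index[i]
    if (is.na(p)) {
      rots[[i]] <- Ri
      pos[i, ] <- pose$root_translation
    } else {
      G <- rots[[p]] %*% Ri
      rots[[i]] <- G
      d <- skeleton$rest_direction[skeleton$joint_names[i], ]
      pos[i, ] <- pos[p, ] + as.numeric(G %*% d) *
        pose$bone_lengths[[skeleton$joint_names[i]]]
    }
  }
  extra <- setdiff(skeleton$keypoint_names, skeleton$joint_names)
  if (length(extra)) {
    ears <- intersect(extra, c("left_ear", "right_ear"))
    if (length(ears) && all(c("nose", "upper_spine") %in% skeleton$joint_names)) {
      ni <- match("nose", skeleton$joint_names)
      G <- rots[[ni]]
      l_head <- pose$bone_lengths[["nose"]]
      base <- pos["upper_spine", ]
      off <- function(side) base + as.numeric(G %*% (l_head *
        c(.ear_frac$along, side * .ear_frac$lateral, .ear_frac$up)))
      epos <- rbind(left_ear = off(+1), right_ear = off(-1))
      pos <- rbind(pos, epos[ears, , drop = FALSE])
    }
  }
  pos <- pos[skeleton$keypoint_names[skeleton$keypoint_names %in% rownames(pos)],
             , drop = FALSE]
  keypoints3d(pos)
}

#' Construct a 3D keypoint set
#'
#' @param positions numeric matrix n x 3 with rownames (keypoint names), mm.
#' @param valid optional logical vector per row (default all `TRUE`).
#' @return Object of class `keypoints3d`.
#' @export
keypoints3d <- function(positions, valid = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) stop("positions must be n x 3")
  if (is.null(rownames(positions))) stop("positions must have rownames")
  if (is.null(valid)) valid <- rep(TRUE, nrow(positions))
  if (length(valid) != nrow(positions)) stop("valid length mismatch")
  if (any(!is.finite(positions[valid, , drop = FALSE])))
    stop("valid keypoint positions must be finite")
  structure(positions, valid = as.logical(valid), class = "keypoints3d")
}

#' @export
print.keypoints3d <- function(x, ...) {
  cat(sprintf("<keypoints3d> %d points (%d valid)\n",
              nrow(x), sum(attr(x, "valid"))))
  print(unclass(x)[seq_len(min(6L, nrow(x))), , drop = FALSE])
  invisible(x)
}

#' Measure bone lengths from 3D joint positions
#'
#' The inverse of forward kinematics restricted to lengths: the Euclidean
#' distance from each non-root joint to its parent. Rigid motions of the
#' point set leave the result unchanged.
#'
#' @param skeleton a `skeleton_definition`.
#' @param points a `keypoints3d` (or named n x 3 matrix) containing all 18
#'   joint positions.
#' @return Named numeric vector of 17 lengths (mm).
#' @export
bone_lengths_from_keypoints <- function(skeleton, points) {
  pts <- as.matrix(points)
  missing <- setdiff(skeleton$joint_names, rownames(pts))
  if (length(missing))
    stop("missing joint positions: ", paste(missing, collapse = ", "))
  non_root <- setdiff(seq_len(skeleton$n_joints), skeleton$root_index)
  out <- vapply(non_root, function(i) {
    child <- skeleton$joint_names[i]
    parent <- skeleton$joint_names[skeleton$parent_index[i]]
    sqrt(sum((pts[child, ] - pts[parent, ])^2))
  }, numeric(1))
  names(out) <- skeleton$joint_names[non_root]
  out
}

#' Serialize a skeleton definition to YAML
#'
#' @param skeleton a `skeleton_definition`.
#' @param path output file path.
#' @export
save_skeleton <- function(skeleton, path) {
  non_root <- skeleton$joint_names[-skeleton$root_index]
  obj <- list(
    joint_names = skeleton$joint_names,
    parents = ifelse(is.na(skeleton$parent_index), "",
                     skeleton$joint_names[skeleton$parent_index]),
    rest_direction = lapply(non_root, function(nm)
      as.numeric(skeleton$rest_direction[nm, ])),
    keypoint_names = skeleton$keypoint_names
  )
  names(obj$rest_direction) <- non_root
  yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

#' Load a skeleton definition from YAML
#'
#' @param path file written by [save_skeleton()], or the packaged default
#'   (`system.file("extdata", "mouse_skeleton.yaml", package = "mouselift")`).
#' @return A `skeleton_definition`.
#' @export
load_skeleton <- function(path) {
  obj <- yaml::read_yaml(path)
  parents <- match(obj$parents, obj$joint_names)
  rd <- do.call(rbind, obj$rest_direction)
  rownames(rd) <- names(obj$rest_direction)
  skeleton_definition(obj$joint_names, parents, rd, obj$keypoint_names)
}

#' @export
print.skeleton_definition <- function(x, ...) {
  cat(sprintf("<skeleton_definition> %d joints (root: %s), %d keypoints, %d DOF\n",
              x$n_joints, x$joint_names[x$root_index],
              length(x$keypoint_names), count_dof(x)))
  invisible(x)
}
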