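# Fixtures built in code: a unit-cube mesh, simple bones for posing, and
# random rigid transforms.

unit_cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  # 12 triangles, two per face, outward winding not required by the tests
  f <- rbind(
    c(1, 2, 4), c(1, 4, 3),      # z = 0
    c(5, 8, 6), c(5, 7, 8),      # z = 1
    c(1, 6, 2), c(1, 5, 6),      # y = 0
    c(3, 4, 8), c(3, 8, 7),      # y = 1
    c(1, 3, 7), c(1, 7, 5),      # x = 0
    c(2, 6, 8), c(2, 8, 4))      # x = 1
  make_mesh(v, f)
}

# Metacarpal/trapezium pair with elliptical facets; the metacarpal is
# displaced by a known rigid motion so posing has real work to do.
toy_bone_pair <- function(displace = TRUE) {
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  facet_t <- cbind(5.5 * cos(th), 4 * sin(th), 0)
  tilt <- tmctorque:::rotation_about_axis(c(1, 0, 0), 10)
  facet_m <- cbind(5.3 * cos(th), 3.9 * sin(th), 0) %*% t(tilt)
  ori <- rbind(ORI1 = c(-1.5, 9, -0.7), ORI2 = c(-3, 8, -1),
               ORI3 = c(0.5, 7.5, -1.3))
  ins <- rbind(INS1 = c(6, 3.6, 34), INS2 = c(6.4, 3.2, 28),
               INS3 = c(6, 2.8, 22), MC1_HEAD = c(0, 0, 45))
  if (displace) {
    R <- tmctorque:::rotation_about_axis(c(1, 0.4, -0.2), 35)
    tv <- c(20, -5, 33)
    ins <- sweep(ins %*% t(R), 2, tv, `+`)
    facet_m <- sweep(facet_m %*% t(R), 2, tv, `+`)
  }
  list(metacarpal = bone_model("mc1", "right", ins, facet = facet_m),
       trapezium = bone_model("trap", "right", ori, facet = facet_t))
}

rand_rotation <- function() {
  M <- matrix(rnorm(9), 3, 3)
  q <- qr.Q(qr(M))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

apply_rigid_bone <- function(bone, R, tv) {
  ap <- function(m) {
    if (is.null(m)) return(NULL)
    out <- sweep(m %*% t(R), 2, tv, `+`)
    dimnames(out) <- dimnames(m)
    out
  }
  bone$landmarks <- ap(bone$landmarks)
  bone$facet <- ap(bone$facet)
  bone
}

# All pairwise distances between metacarpal + trapezium landmarks of a
# posed configuration (rigid-invariant fingerprint).
posed_distances <- function(posed) {
  pts <- rbind(posed$metacarpal$landmarks, posed$trapezium$landmarks,
               j = posed$j)
  as.numeric(dist(pts))
}

# A small closed toy outline configuration for shape tests.
toy_entheseal <- function(proj = 1, noise = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bpfun <- function(theta) {
    lobe <- ((1 + cos(theta)) / 2)^3
    c(proj * lobe, (2 + 0.3 * proj * lobe) * sin(theta), 6 * cos(theta))
  }
  th_fix <- seq(0, 2 * pi, length.out = 7)[-7]
  fixed <- t(vapply(th_fix, bpfun, numeric(3)))
  rownames(fixed) <- paste0("F", 1:6)
  curves <- lapply(1:6, function(k) {
    tt <- seq(th_fix[k], th_fix[k] + pi / 3, length.out = 12)[2:11]
    pts <- t(vapply(tt, bpfun, numeric(3)))
    pts + matrix(rnorm(length(pts), 0, noise), nrow(pts), 3)
  })
  entheseal_config("toy", fixed + matrix(rnorm(18, 0, noise), 6, 3), curves)
}
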