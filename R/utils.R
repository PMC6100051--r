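# eV <-> nm conversion constant (h*c in nm.eV)
.hc_nm_eV <- 1239.841984

# nm per Bohr radius
.nm_per_bohr <- 0.052917721

# Atom names making up the minimal synthetic fluorophore moiety
.fluorophoreAtoms <- c("C1", "N1", "C2", "C3", "C4")

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's state afterwards so generators never perturb the global stream.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Rotation matrices (right-handed, radians)
.rotY <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, 0, -s, 0, 1, 0, s, 0, c), 3, 3, byrow = TRUE)
}

.rotZ <- function(phi) {
  c <- cos(phi); s <- sin(phi)
  matrix(c(c, -s, 0, s, c, 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

# Mass-weighted centre of mass of a coordinate matrix (n x 3)
.com <- function(pos, mass) {
  if (length(mass) != nrow(pos)) stop("mass/position length mismatch")
  tm <- sum(mass)
  if (tm <= 0) stop("zero total mass in centre-of-mass computation")
  colSums(pos * mass) / tm
}

# Angle in degrees between two 3-vectors, clamped against rounding
.vecAngleDeg <- function(a, b) {
  ct <- sum(a * b) / sqrt(sum(a * a) * sum(b * b))
  .rad2deg(acos(pmin(1, pmax(-1, ct))))
}

.assertScalarNumeric <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", what))
  invisible(x)
}
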