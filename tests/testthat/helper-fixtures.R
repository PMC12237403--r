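# Shared fixture builders. Everything is generated in code at test time.

# Render an isotropic Gaussian spot of given integrated intensity on a
# matrix, evaluated at 0-based pixel centres. Written independently of the
# package's renderer so the two can check each other.
gaussSpot <- function(h, w, xPx, yPx, sigmaPx, photons) {
  xs <- 0:(w - 1); ys <- 0:(h - 1)
  amp <- photons / (2 * pi * sigmaPx^2)
  amp * outer(exp(-(ys - yPx)^2 / (2 * sigmaPx^2)),
              exp(-(xs - xPx)^2 / (2 * sigmaPx^2)))
}

# Channel-shift matrix in the layout simulationConfig() expects.
shiftMatrix <- function(cis = c(0, 0), trans = c(0, 0), cargo = c(0, 0)) {
  matrix(c(cis[1], trans[1], cargo[1], cis[2], trans[2], cargo[2]), 3, 2,
         dimnames = list(c("cis", "trans", "cargo"), c("dx", "dy")))
}

# Chase-time grid used in the kinetic simulations (8 timepoints).
kineticTimepoints <- c(5, 10, 15, 20, 30, 40, 50, 60)

# Exact-centre LQ of one simulated stack, straight from the ground truth.
truthLQ <- function(truth, id) {
  s <- truth[truth$stack_id == id, ]
  co <- function(ch) unlist(s[s$channel == ch, c("x_nm", "y_nm")])
  computeLQ(co("cargo"), co("cis"), co("trans"))$lq
}
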