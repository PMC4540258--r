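# Small in-code fixtures shared across tests.

# three-sample, two-bin library with distinct groups
tiny_library <- function() {
  fa_library(rbind(c(0.2, 0.8), c(0.4, 0.6), c(0.6, 0.4)),
             meta = data.frame(sample_id = c("a", "b", "c"),
                               group = c("g1", "g1", "g2")),
             bins = c("16:0", "18:1"))
}

# taxon-level prey basis built from the packaged reference means
taxon_basis <- function(taxa = c("fish", "mollusc", "frog", "crayfish"),
                        eps = 1e-5) {
  ref <- reference_signatures()
  mom <- fadiet:::.taxon_moments(ref, taxa)
  prey_basis(mom$mean, eps = eps)
}

# exhaustive simplex grid with resolution `step` over k taxa (k = 2 or 3)
simplex_grid <- function(k, step) {
  m <- round(1 / step)
  if (k == 2) {
    i <- 0:m
    cbind(i, m - i) / m
  } else if (k == 3) {
    g <- expand.grid(i = 0:m, j = 0:m)
    g <- g[g$i + g$j <= m, ]
    cbind(g$i, g$j, m - g$i - g$j) / m
  } else {
    stop("grid oracle implemented for k <= 3")
  }
}

# brute-force KL minimization over a simplex grid: returns the minimum
# objective and the minimizing grid point
grid_min_kl <- function(y, basis, step) {
  P <- simplex_grid(ncol(basis$M), step)
  U <- P %*% t(basis$M * basis$calibration)
  U <- U / rowSums(U)
  ym <- matrix(y, nrow(U), length(y), byrow = TRUE)
  d <- rowSums((U - ym) * (log(U) - log(ym)))
  i <- which.min(d)
  list(value = d[i], p = P[i, ])
}
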