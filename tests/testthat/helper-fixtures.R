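# Small in-code fixtures shared across tests.

# hand-built bag_set: 2 crowns, 3 pixels, 5 bands
toy_bagset <- function() {
  bag_set(matrix(seq(0.1, 1.5, by = 0.1), nrow = 3, ncol = 5),
          crown_id = c("crownA", "crownA", "crownB"),
          genus = c("PI", "PI", "QU"),
          species = c("PIPA", "PIPA", "QULA"),
          wavelengths = c(400, 500, 600, 700, 800))
}

# identity-background detector with a given (already unit) whitened signature
identity_detector <- function(s) {
  d <- length(s)
  bg <- structure(list(mean = rep(0, d), cov = diag(d), U = diag(d),
                       D = rep(1, d), lambda = 0),
                  class = "background_model")
  miace_signature(s, bg, whitened = TRUE)
}

# random positive/negative bags around planted directions
random_bags <- function(n_bags, n_inst, d, direction = NULL, sd = 1,
                        mu = rep(0, d)) {
  replicate(n_bags, {
    x <- matrix(rnorm(n_inst * d, sd = sd), n_inst, d)
    x <- sweep(x, 2, mu, "+")
    if (!is.null(direction)) x[1, ] <- x[1, ] + direction
    x
  }, simplify = FALSE)
}

# genus map mirroring a two-genus hierarchy with 1 and 3 species
toy_genus_map <- function() list(AC = "ACRU", PI = c("PIEL", "PIPA", "PITA"))
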