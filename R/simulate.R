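#' Configuration for the synthetic bag generator
#'
#' Collects the parameters of the Gaussian background plus scaled-target
#' generative model used to emulate crown-labeled hyperspectral data. Each
#' class `c` has a target signature `s_c`; a target-bearing pixel is drawn
#' from `N(alpha * s_c + mu_b, sigma1sq * Sigma_b)` with abundance
#' `alpha != 0` drawn uniformly from `abundance`, and a pure background pixel
#' from `N(mu_b, sigma1sq * Sigma_b)`. Every positive bag carries at least
#' one target pixel; `target_fraction` controls how many, and
#' `contamination_fraction` replaces background pixels with draws from a
#' different class's target model, emulating mislabeled crown pixels.
#'
#' Defaults describe a modest desk-scale dataset: 50 bands, smooth
#' exponentially correlated background noise (a stand-in for spectrally
#' correlated vegetation reflectance), 25 crowns per class with 10-30 pixels
#' each, half of the pixels in a crown carrying the target.
#'
#' @param n_classes number of species classes.
#' @param n_bands number of spectral bands `d`.
#' @param class_signatures optional `n_classes x n_bands` matrix of target
#'   signatures; by default smooth random directions scaled to norm
#'   `signature_scale`.
#' @param signature_scale Euclidean norm of each default signature
#'   (reflectance units).
#' @param background_mean optional length-`d` background mean; default a
#'   smooth synthetic vegetation-like curve around 0.25 reflectance.
#' @param background_cov optional `d x d` background covariance; default
#'   `bg_sd^2 * rho^|i-j|`.
#' @param bg_sd per-band background standard deviation.
#' @param rho neighbouring-band correlation of the default background.
#' @param sigma1sq global noise variance multiplier.
#' @param abundance `c(lo, hi)` interval for the target abundance `alpha`;
#'   must not contain 0.
#' @param bags_per_class number of crowns per class.
#' @param instances_per_bag `c(lo, hi)` range of pixels per crown.
#' @param target_fraction fraction of a positive bag's pixels carrying the
#'   target, in `(0, 1]` (at least one pixel is always a target).
#' @param contamination_fraction fraction of a bag's pixels replaced by
#'   another class's target pixels, in `[0, 1)`.
#' @param wavelengths optional band axis (nm); default an even grid from
#'   400 to 2500 nm.
#' @param seed integer seed making generation fully reproducible.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_classes = 4, n_bands = 50,
                         class_signatures = NULL, signature_scale = 0.15,
                         background_mean = NULL, background_cov = NULL,
                         bg_sd = 0.05, rho = 0.9, sigma1sq = 1,
                         abundance = c(0.5, 1.5),
                         bags_per_class = 25, instances_per_bag = c(10, 30),
                         target_fraction = 0.5, contamination_fraction = 0,
                         wavelengths = NULL, seed = 1L) {
  if (length(abundance) == 1L) abundance <- rep(abundance, 2)
  if (abundance[1] <= 0 && abundance[2] >= 0)
    stop("abundance interval must not contain 0 (alpha != 0)")
  if (target_fraction <= 0 || target_fraction > 1)
    stop("target_fraction must lie in (0, 1]")
  if (contamination_fraction < 0 || contamination_fraction >= 1)
    stop("contamination_fraction must lie in [0, 1)")
  if (is.null(wavelengths))
    wavelengths <- seq(400, 2500, length.out = n_bands)
  structure(list(n_classes = n_classes, n_bands = n_bands,
                 class_signatures = class_signatures,
                 signature_scale = signature_scale,
                 background_mean = background_mean,
                 background_cov = background_cov,
                 bg_sd = bg_sd, rho = rho, sigma1sq = sigma1sq,
                 abundance = abundance, bags_per_class = bags_per_class,
                 instances_per_bag = instances_per_bag,
                 target_fraction = target_fraction,
                 contamination_fraction = contamination_fraction,
                 wavelengths = wavelengths, seed = as.integer(seed)),
            class = "synth_config")
}

# smooth random curve: iid normals blurred with a moving average
smooth_curve <- function(d, width = max(3L, d %/% 10L)) {
  z <- stats::rnorm(d + width)
  stats::filter(z, rep(1 / width, width), sides = 2)[seq_len(d) + width %/% 2]
}

#' Generate synthetic crown bags
#'
#' Draws a [bag_set] from the generative model described in [synth_config()].
#' Class labels are `C1 ... Cn` at both genus and species level (see
#' [simulate_two_level()] for a genuine hierarchy). The per-instance ground
#' truth (role, abundance, source class) is attached as attribute
#' `"ground_truth"`, and the true class signatures and background model as
#' attributes `"signatures"`, `"background_mean"`, `"background_cov"`.
#'
#' @param config a [synth_config()].
#' @return A `bag_set` (empty request gives a zero-bag error from the
#'   container), fully reproducible from `config$seed`.
#' @export
simulate_bags <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  cf <- config
  d <- cf$n_bands
  with_preserved_seed({
    set.seed(cf$seed)
    mu_b <- cf$background_mean
    if (is.null(mu_b))
      mu_b <- 0.25 + 0.1 * sin(seq(0, 3 * pi, length.out = d)) +
        0.02 * smooth_curve(d)
    Sigma <- cf$background_cov
    if (is.null(Sigma))
      Sigma <- cf$bg_sd^2 * cf$rho^abs(outer(seq_len(d), seq_len(d), "-"))
    ch <- tryCatch(chol(cf$sigma1sq * Sigma),
                   error = function(e) stop("background covariance not positive definite"))
    S <- cf$class_signatures
    if (is.null(S)) {
      S <- t(replicate(cf$n_classes, {
        v <- smooth_curve(d)
        v / sqrt(sum(v^2)) * cf$signature_scale
      }))
    }
    if (nrow(S) != cf$n_classes || ncol(S) != d)
      stop("class_signatures must be n_classes x n_bands")

    classes <- paste0("C", seq_len(cf$n_classes))
    spectra <- list(); crown <- character(0); lab <- character(0)
    gt <- list()
    bag_no <- 0L
    draw_noise <- function(n) matrix(stats::rnorm(n * d), n, d) %*% ch
    draw_alpha <- function(n) stats::runif(n, cf$abundance[1], cf$abundance[2])

    for (c in seq_len(cf$n_classes)) {
      for (b in seq_len(cf$bags_per_class)) {
        bag_no <- bag_no + 1L
        id <- sprintf("%s_bag%02d", classes[c], b)
        n <- if (cf$instances_per_bag[1] == cf$instances_per_bag[2])
          cf$instances_per_bag[1] else
          sample(cf$instances_per_bag[1]:cf$instances_per_bag[2], 1L)
        n_t <- max(1L, ceiling(cf$target_fraction * n))
        role <- c(rep("target", n_t), rep("background", n - n_t))
        alpha <- c(draw_alpha(n_t), rep(0, n - n_t))
        src <- rep(classes[c], n)
        src[role == "background"] <- ""
        X <- draw_noise(n) + rep(mu_b, each = n)
        X[seq_len(n_t), ] <- X[seq_len(n_t), , drop = FALSE] +
          alpha[seq_len(n_t)] %o% S[c, ]
        # contamination: background pixels replaced by another class's targets
        n_con <- floor(cf$contamination_fraction * n)
        n_con <- min(n_con, n - n_t)   # never displace the guaranteed targets
        if (n_con > 0L && cf$n_classes > 1L) {
          rows <- n_t + seq_len(n_con)
          oth <- sample(setdiff(seq_len(cf$n_classes), c), n_con, replace = TRUE)
          a <- draw_alpha(n_con)
          X[rows, ] <- draw_noise(n_con) + rep(mu_b, each = n_con) + a * S[oth, , drop = FALSE]
          role[rows] <- "contamination"
          alpha[rows] <- a
          src[rows] <- classes[oth]
        }
        spectra[[bag_no]] <- X
        crown <- c(crown, rep(id, n))
        lab <- c(lab, rep(classes[c], n))
        gt[[bag_no]] <- data.frame(bag_id = id, instance = seq_len(n),
                                   role = role, alpha = alpha,
                                   source_class = src, stringsAsFactors = FALSE)
      }
    }
    if (bag_no == 0L) stop("zero bags requested")
    out <- bag_set(do.call(rbind, spectra), crown,
                   genus = lab, species = lab, wavelengths = cf$wavelengths)
    attr(out, "ground_truth") <- do.call(rbind, gt)
    attr(out, "signatures") <- S
    attr(out, "background_mean") <- mu_b
    attr(out, "background_cov") <- cf$sigma1sq * Sigma
    out
  })
}

#' Generate two-level (genus and species) synthetic bags
#'
#' Builds a species-level bag set whose species signatures cluster by genus:
#' each genus has a base direction and each species signature is the
#' normalized mix `similarity * genus + (1 - similarity) * own`, so that as
#' `similarity` approaches 1 the species of a genus become spectrally
#' indistinguishable while genera stay separated. This mirrors crown data
#' where congeneric species are much harder to tell apart than genera.
#'
#' @param genus_map named list mapping genus codes to character vectors of
#'   species codes (at least one species per genus).
#' @param config a [synth_config()]; `n_classes` is overridden by the total
#'   species count and default class signatures are replaced by the
#'   genus-structured ones.
#' @param similarity within-genus signature similarity in `[0, 1)`.
#' @return A `bag_set` with genus and species labels per crown, ground truth
#'   attached as in [simulate_bags()].
#' @export
simulate_two_level <- function(genus_map, config = synth_config(),
                               similarity = 0.7) {
  stopifnot(is.list(genus_map), length(genus_map) >= 1)
  if (any(lengths(genus_map) == 0L)) stop("genus with zero species")
  if (similarity < 0 || similarity >= 1)
    stop("similarity must lie in [0, 1)")
  species <- unlist(genus_map, use.names = FALSE)
  if (anyDuplicated(species)) stop("duplicate species codes across genera")
  genus_of <- rep(names(genus_map), lengths(genus_map))
  d <- config$n_bands
  cf <- config
  cf$n_classes <- length(species)
  sig <- with_preserved_seed({
    set.seed(cf$seed + 7654321L)
    gbase <- t(replicate(length(genus_map), {
      v <- smooth_curve(d); v / sqrt(sum(v^2))
    }))
    t(vapply(seq_along(species), function(i) {
      own <- smooth_curve(d); own <- own / sqrt(sum(own^2))
      v <- similarity * gbase[match(genus_of[i], names(genus_map)), ] +
        (1 - similarity) * own
      v / sqrt(sum(v^2)) * cf$signature_scale
    }, numeric(d)))
  })
  cf$class_signatures <- sig
  out <- simulate_bags(cf)
  # relabel C1..Cn -> species and genus codes
  k <- match(out$bags$species, paste0("C", seq_along(species)))
  out$bags$species <- species[k]
  out$bags$genus <- genus_of[k]
  gt <- attr(out, "ground_truth")
  m <- match(gt$source_class, paste0("C", seq_along(species)))
  gt$source_class[!is.na(m)] <- species[m[!is.na(m)]]
  attr(out, "ground_truth") <- gt
  rownames(attr(out, "signatures")) <- species
  out
}
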