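#' LRR level model
#'
#' Per copy number `x`, the log R ratio level of a clone is drawn
#' `r_x ~ N(mu_x, sigma_x)`, independently per SNP and per clone.  The `mu`
#' table is in LRR units with `mu[2] = 0` by convention (a diploid genome at
#' zero); the default table approximates observed Illumina levels and every
#' entry is overridable.  `baseline_shift` is the sample-wide displacement
#' `l` of the LRR zero level caused by non-diploid average ploidy.
#'
#' @param mu named numeric vector, copy number -> expected LRR.
#' @param sigma scalar or named vector of per-copy-number standard
#'   deviations.
#' @param baseline_shift sample-wide LRR shift `l`.
#' @return An object of class `lrr_model`.
#' @export
lrr_model <- function(mu = c(`0` = -2.00, `1` = -0.55, `2` = 0.00,
                             `3` = 0.30, `4` = 0.54, `5` = 0.70),
                      sigma = 0.2, baseline_shift = 0) {
  if (is.null(names(mu))) stop_("lrr_model: mu must be named by copy number")
  if (any(sigma < 0)) stop_("lrr_model: sigma must be >= 0")
  structure(list(mu = mu, sigma = sigma, baseline_shift = baseline_shift),
            class = "lrr_model")
}

lookup_cn <- function(table, x, what) {
  idx <- match(as.character(x), names(table))
  if (anyNA(idx)) {
    miss <- unique(x[is.na(idx)])
    stop_("no %s entry for copy number %s", what, paste(miss, collapse = ", "))
  }
  unname(table[idx])
}

#' Autocorrelated LRR bias model
#'
#' The probe-to-probe autocorrelated component of the LRR signal (genomic
#' waves) follows a Box-Jenkins ARMA model with Gaussian innovations.  The
#' default used by [sample_config()] is a slow AR(1) (coefficient 0.995)
#' with the innovation variance chosen for a marginal standard deviation of
#' 0.05.
#'
#' @param ar,ma autoregressive / moving-average coefficient vectors (empty
#'   for white noise).
#' @param innovation_sd standard deviation of the Gaussian innovations
#'   (`0` switches the component off exactly).
#' @return An object of class `arma_model`.
#' @export
arma_model <- function(ar = numeric(), ma = numeric(), innovation_sd = 0) {
  ar <- as.numeric(ar); ma <- as.numeric(ma)
  if (length(ar) && any(Mod(polyroot(c(1, -ar))) <= 1))
    stop_("arma_model: AR coefficients are not stationary")
  if (innovation_sd < 0) stop_("arma_model: innovation_sd must be >= 0")
  structure(list(ar = ar, ma = ma, innovation_sd = innovation_sd),
            class = "arma_model")
}

#' Simulate a stationary ARMA series
#'
#' Wraps [stats::arima.sim()] with a burn-in of at least ten times the model
#' order (longer for near-unit-root AR parts) so the returned stretch is
#' effectively stationary.
#'
#' @param model an [arma_model()].
#' @param n series length.
#' @param seed optional integer seed.
#' @return numeric vector of length `n`.
#' @export
arma_series <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "arma_model"))
  if (!is_count(n) || n < 1) stop_("arma_series: n must be a positive integer")
  if (model$innovation_sd == 0) return(numeric(n))
  p <- length(model$ar); q <- length(model$ma)
  with_seed(seed, {
    if (p + q == 0L) return(stats::rnorm(n, 0, model$innovation_sd))
    burn <- 10L * (p + q)
    if (p > 0L) {
      minroot <- min(Mod(polyroot(c(1, -model$ar))))
      burn <- burn + min(ceiling(6 / log(minroot)), 20000L)
    }
    mod <- list()
    if (p > 0L) mod$ar <- model$ar
    if (q > 0L) mod$ma <- model$ma
    as.numeric(stats::arima.sim(mod, n = n, sd = model$innovation_sd,
                                n.start = burn))
  })
}

#' Draw per-SNP, per-clone LRR levels
#'
#' @param x integer vector or matrix of copy numbers (SNPs x cell types).
#' @param model an [lrr_model()].
#' @param seed optional integer seed.
#' @return numeric object shaped like `x` with independent
#'   `N(mu_x, sigma_x)` draws.
#' @export
draw_lrr_levels <- function(x, model, seed = NULL) {
  stopifnot(inherits(model, "lrr_model"))
  mu <- lookup_cn(model$mu, as.vector(x), "mu")
  sig <- if (length(model$sigma) == 1L) rep(model$sigma, length(mu))
         else lookup_cn(model$sigma, as.vector(x), "sigma")
  r <- with_seed(seed, stats::rnorm(length(mu), mu, sig))
  if (is.matrix(x)) matrix(r, nrow = nrow(x)) else r
}

as_weight_matrix <- function(weights, n, k) {
  w <- if (is.matrix(weights)) weights
       else matrix(rep(weights, each = n), nrow = n)
  if (nrow(w) != n || ncol(w) != k)
    stop_("weights dimensions (%d x %d) do not match genotypes (%d x %d)",
          nrow(w), ncol(w), n, k)
  if (any(w < 0) || any(abs(rowSums(w) - 1) > 1e-8))
    stop_("cell-type proportions must be non-negative and sum to one at every locus")
  w
}

#' Synthesize the LRR signal
#'
#' `lrr_i = sum_j w_ij * r_{x_ij} + l + c_i`: the mixture of per-clone LRR
#' levels, plus the sample baseline shift and the autocorrelated bias.
#'
#' @param genotypes a `genotype_matrix` (see [assign_region_genotypes()]).
#' @param weights per-cell-type proportions: a vector (constant along the
#'   region) or an SNPs x cell-types matrix; rows must sum to 1.
#' @param model an [lrr_model()].
#' @param arma optional [arma_model()] for the autocorrelated bias.
#' @param seed optional integer seed.
#' @return numeric LRR vector.
#' @export
synthesize_lrr <- function(genotypes, weights, model, arma = NULL, seed = NULL) {
  n <- nrow(genotypes$x)
  w <- as_weight_matrix(weights, n, ncol(genotypes$x))
  with_seed(seed, {
    r <- draw_lrr_levels(genotypes$x, model)
    ci <- if (is.null(arma)) 0 else arma_series(arma, n)
    rowSums(w * r) + model$baseline_shift + ci
  })
}

# Shared BAF noise kernel: noiseless values in {0,1} get the half-normal /
# point-mass mixture (exact extreme with probability pi), heterozygous
# values get a full Gaussian.  Emitted values are clipped to [0,1].
add_baf_noise <- function(b, noise) {
  out <- b
  hom0 <- which(!is.na(b) & b == 0)
  hom1 <- which(!is.na(b) & b == 1)
  het <- which(!is.na(b) & b > 0 & b < 1)
  if (length(hom0)) {
    keep <- stats::runif(length(hom0)) < noise$pi_extreme
    out[hom0] <- ifelse(keep, 0,
                        abs(stats::rnorm(length(hom0), 0, noise$sigma_ho)))
  }
  if (length(hom1)) {
    keep <- stats::runif(length(hom1)) < noise$pi_extreme
    out[hom1] <- ifelse(keep, 1,
                        1 - abs(stats::rnorm(length(hom1), 0, noise$sigma_ho)))
  }
  if (length(het))
    out[het] <- b[het] + stats::rnorm(length(het), 0, noise$sigma_he)
  pmin(pmax(out, 0), 1)
}

#' BAF noise model
#'
#' Heterozygous BAF values receive full-Gaussian noise of standard deviation
#' `sigma_he`; homozygous values (noiseless BAF exactly 0 or 1) are a
#' mixture of a point mass at the extreme (probability `pi_extreme`) and a
#' half-Gaussian of standard deviation `sigma_ho` pointing into the unit
#' interval.  `sigma_ho` defaults to half of `sigma_he`, as observed on real
#' arrays.
#'
#' @param sigma_he heterozygous noise sd.
#' @param sigma_ho homozygous half-Gaussian sd.
#' @param pi_extreme proportion of homozygous probes forced to exactly 0/1.
#' @return An object of class `baf_noise_model`.
#' @export
baf_noise_model <- function(sigma_he = 0.03, sigma_ho = 0.015,
                            pi_extreme = 0.30) {
  if (sigma_he < 0 || sigma_ho < 0)
    stop_("baf_noise_model: sigmas must be >= 0")
  if (pi_extreme < 0 || pi_extreme > 1)
    stop_("baf_noise_model: pi_extreme must lie in [0, 1]")
  structure(list(sigma_he = sigma_he, sigma_ho = sigma_ho,
                 pi_extreme = pi_extreme),
            class = "baf_noise_model")
}

#' Synthesize the BAF signal
#'
#' The noiseless value is the weighted allelic ratio
#' `b_i = sum_j w_ij z_ij / sum_j w_ij x_ij`; noise is then added by the
#' homozygous/heterozygous mixture of [baf_noise_model()].  SNPs whose
#' weighted total copy number is zero (homozygous deletion in every
#' contributing cell type) have no defined BAF and are emitted as `NA` with
#' a warning.
#'
#' @param genotypes a `genotype_matrix`.
#' @param weights as in [synthesize_lrr()].
#' @param noise a [baf_noise_model()].
#' @param seed optional integer seed.
#' @return numeric BAF vector in `[0, 1]` (`NA` where undefined).
#' @export
synthesize_baf <- function(genotypes, weights, noise, seed = NULL) {
  n <- nrow(genotypes$x)
  w <- as_weight_matrix(weights, n, ncol(genotypes$x))
  denom <- rowSums(w * genotypes$x)
  b <- rowSums(w * genotypes$z) / denom
  if (any(denom == 0)) {
    warning(sprintf("%d SNP(s) with zero weighted copy number: BAF undefined",
                    sum(denom == 0)), call. = FALSE)
    b[denom == 0] <- NA_real_
  }
  with_seed(seed, add_baf_noise(b, noise))
}

#' Noiseless expected signals
#'
#' Closed-form evaluation of the LRR and BAF mixtures with every noise term
#' zeroed: per-clone levels at their means `mu_x`, no autocorrelated bias,
#' and the noiseless allelic ratio.  Equals the synthesized signals
#' bit-for-bit when all sigmas and the ARMA innovation sd are 0 and
#' `pi_extreme = 1`.
#'
#' @param genotypes a `genotype_matrix`.
#' @param weights as in [synthesize_lrr()].
#' @param model an [lrr_model()] (supplies `mu` and `baseline_shift`).
#' @return list with numeric vectors `lrr` and `baf`.
#' @export
expected_signals <- function(genotypes, weights, model) {
  n <- nrow(genotypes$x)
  w <- as_weight_matrix(weights, n, ncol(genotypes$x))
  mu <- matrix(lookup_cn(model$mu, as.vector(genotypes$x), "mu"), nrow = n)
  lrr <- rowSums(w * mu) + model$baseline_shift
  denom <- rowSums(w * genotypes$x)
  baf <- rowSums(w * genotypes$z) / denom
  baf[denom == 0] <- NA_real_
  list(lrr = lrr, baf = baf)
}
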