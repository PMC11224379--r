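# Metabolites with a pure reductive/oxidative labeling signature under
# U-13C5/15N2 glutamine, and their total label capacity (carbons + nitrogens).
.mid_signatures <- list(
  citrate   = list(capacity = 6L, reductive = 5L, oxidative = 4L),
  fumarate  = list(capacity = 4L, reductive = 3L, oxidative = c(4L, 2L)),
  malate    = list(capacity = 4L, reductive = 3L, oxidative = c(4L, 2L)),
  aspartate = list(capacity = 5L, reductive = 3L, oxidative = c(4L, 5L))
)

#' Planted truth for a mass-isotopologue simulation
#'
#' @param reductive_fraction fraction of the labeled pool routed through
#'   reductive carboxylation, in [0, 1]; the remainder is oxidative.
#' @param labeled_fraction total labeled mass fraction (the rest sits at m+0).
#' @param n_replicates replicates to draw.
#' @param noise_sd standard deviation of the additive truncated-Gaussian
#'   fraction noise (>= 0).
#' @return a \code{flux_truth} list.
#' @export
flux_truth <- function(reductive_fraction, labeled_fraction = 0.35,
                       n_replicates = 4, noise_sd = 0.01) {
  stopifnot(reductive_fraction >= 0, reductive_fraction <= 1,
            labeled_fraction > 0, labeled_fraction <= 1,
            n_replicates >= 1, noise_sd >= 0)
  structure(list(reductive_fraction = reductive_fraction,
                 labeled_fraction = labeled_fraction,
                 n_replicates = as.integer(n_replicates),
                 noise_sd = noise_sd),
            class = "flux_truth")
}

#' Simulate mass-isotopologue distributions from planted flux fractions
#'
#' The expected MID places \code{1 - labeled_fraction} at m+0 and splits the
#' labeled mass between the metabolite's pure reductive signature shift
#' (weight \code{reductive_fraction}) and its oxidative signature shifts
#' (weight \code{1 - reductive_fraction}, spread equally when the oxidative
#' signature has two shifts). Replicates add truncated-Gaussian noise
#' (negative fractions clipped at 0) and are renormalized to sum to 1.
#'
#' @param metabolite one of citrate, fumarate, malate, aspartate (the
#'   metabolites with a pure pathway signature).
#' @param truth a \code{flux_truth}.
#' @param seed integer seed.
#' @return data.frame (metabolite, mass_shift, replicate, fraction); fractions
#'   sum to 1 within each replicate.
#' @export
simulate_mid <- function(metabolite, truth, seed) {
  stopifnot(inherits(truth, "flux_truth"))
  sig <- .mid_signatures[[metabolite]]
  if (is.null(sig)) {
    stop("unknown metabolite '", metabolite, "'; signatures are defined for: ",
         paste(names(.mid_signatures), collapse = ", "))
  }
  shifts <- 0:sig$capacity
  expected <- numeric(length(shifts))
  expected[1L] <- 1 - truth$labeled_fraction
  expected[sig$reductive + 1L] <- expected[sig$reductive + 1L] +
    truth$labeled_fraction * truth$reductive_fraction
  ox_w <- truth$labeled_fraction * (1 - truth$reductive_fraction) /
    length(sig$oxidative)
  for (s in sig$oxidative) expected[s + 1L] <- expected[s + 1L] + ox_w

  with_rng_seed(seed, {
    reps <- lapply(seq_len(truth$n_replicates), function(r) {
      f <- expected
      if (truth$noise_sd > 0) {
        f <- pmax(0, f + stats::rnorm(length(f), 0, truth$noise_sd))
        if (sum(f) == 0) f <- expected
      }
      data.frame(metabolite = metabolite, mass_shift = shifts, replicate = r,
                 fraction = f / sum(f), stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, reps)
    rownames(out) <- NULL
    out
  })
}
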