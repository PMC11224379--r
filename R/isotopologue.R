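#' Default isotopologue-to-pathway attribution table
#'
#' Frozen classification of glutamine-derived mass isotopologues (total mass
#' shift, carbons + nitrogens, under U-13C5/15N2 glutamine) into reductive
#' carboxylation versus oxidative glutaminolysis signatures: citrate m+5
#' reductive / m+4 oxidative; fumarate and malate m+3 reductive / m+4 and m+2
#' oxidative; aspartate m+3 reductive / m+4 and m+5 oxidative (m+5 via
#' transamination with labeled amine); glutamate m+6 and alpha-ketoglutarate
#' m+5 are direct-precursor labels (class "shared"). m+0 is unlabeled and any
#' other labeled shift is "shared" between pathways. Succinate carries no
#' pathway-specific class. The table can be replaced to support other
#' tracers.
#'
#' @return data.frame (metabolite, mass_shift, class) plus attribute
#'   \code{"metabolites"}: the known metabolite set.
#' @export
default_attribution_table <- function() {
  tab <- rbind(
    data.frame(metabolite = "citrate", mass_shift = c(5L, 4L),
               class = c("reductive", "oxidative")),
    data.frame(metabolite = "fumarate", mass_shift = c(3L, 4L, 2L),
               class = c("reductive", "oxidative", "oxidative")),
    data.frame(metabolite = "malate", mass_shift = c(3L, 4L, 2L),
               class = c("reductive", "oxidative", "oxidative")),
    data.frame(metabolite = "aspartate", mass_shift = c(3L, 4L, 5L),
               class = c("reductive", "oxidative", "oxidative")),
    data.frame(metabolite = "glutamate", mass_shift = 6L, class = "shared"),
    data.frame(metabolite = "alpha-ketoglutarate", mass_shift = 5L,
               class = "shared")
  )
  attr(tab, "metabolites") <- c("citrate", "fumarate", "malate", "aspartate",
                                "succinate", "glutamate",
                                "alpha-ketoglutarate")
  tab
}

#' Normalize raw isotopologue intensities to a mass-isotopologue distribution
#'
#' @param intensities non-negative numeric vector of raw intensities over
#'   mass shifts m+0..m+n (order preserved); must not be all zero.
#' @return numeric vector of fractions summing to 1.
#' @export
normalize_mid <- function(intensities) {
  if (any(intensities < 0)) stop("negative intensities are not allowed")
  tot <- sum(intensities)
  if (tot == 0) stop("all-zero intensity vector cannot be normalized")
  intensities / tot
}

#' Attribute a mass-isotopologue distribution to metabolic pathways
#'
#' Sums the MID fractions by the pathway class of each mass shift:
#' reductive, oxidative, shared (including direct-precursor labels and any
#' labeled shift the table does not classify) and unlabeled (m+0). The four
#' outputs always sum to 1.
#'
#' @param metabolite metabolite name, present in the attribution table's
#'   known set.
#' @param mid numeric vector of fractions over shifts m+0..m+n, or a
#'   data.frame with columns mass_shift and fraction.
#' @param table attribution table (default \code{default_attribution_table}).
#' @return named numeric vector c(reductive, oxidative, shared, unlabeled).
#' @export
attribute_pathways <- function(metabolite, mid,
                               table = default_attribution_table()) {
  known <- attr(table, "metabolites") %||% unique(table$metabolite)
  if (!(metabolite %in% known)) {
    stop("unknown metabolite '", metabolite, "'; known metabolites: ",
         paste(known, collapse = ", "))
  }
  if (is.data.frame(mid)) {
    shifts <- mid$mass_shift
    fr <- mid$fraction
  } else {
    fr <- as.numeric(mid)
    shifts <- if (!is.null(names(mid))) as.integer(names(mid)) else
      seq_along(fr) - 1L
  }
  rows <- table[table$metabolite == metabolite, , drop = FALSE]
  cls <- ifelse(shifts == 0L, "unlabeled",
                rows$class[match(shifts, rows$mass_shift)])
  cls[is.na(cls)] <- "shared"
  out <- c(reductive = 0, oxidative = 0, shared = 0, unlabeled = 0)
  agg <- tapply(fr, cls, sum)
  out[names(agg)] <- agg
  out
}

#' Welch comparison of isotopologue fractions between two groups
#'
#' Per metabolite and mass shift, a two-sided Welch unequal-variance t-test
#' (Welch-Satterthwaite degrees of freedom) of the replicate fractions, with
#' BH adjustment across the shifts within each metabolite. When both groups
#' have zero variance the p-value is 1 for equal means and 0 otherwise.
#'
#' @param mids_a,mids_b data.frames (metabolite, mass_shift, replicate,
#'   fraction) with >= 2 replicates per group per shift.
#' @return data.frame (metabolite, mass_shift, mean_a, mean_b, welch_t, df,
#'   p, bh_q).
#' @export
compare_groups <- function(mids_a, mids_b) {
  key_a <- interaction(mids_a$metabolite, mids_a$mass_shift, drop = TRUE)
  key_b <- interaction(mids_b$metabolite, mids_b$mass_shift, drop = TRUE)
  keys <- sort(unique(c(levels(key_a), levels(key_b))))
  rows <- lapply(keys, function(k) {
    xa <- mids_a$fraction[key_a == k]
    xb <- mids_b$fraction[key_b == k]
    if (length(xa) < 2L || length(xb) < 2L) {
      stop("need >= 2 replicates per group per mass shift (", k, ")")
    }
    w <- .welch(xa, xb)
    parts <- strsplit(k, ".", fixed = TRUE)[[1L]]
    data.frame(metabolite = paste(parts[-length(parts)], collapse = "."),
               mass_shift = as.integer(parts[length(parts)]),
               mean_a = mean(xa), mean_b = mean(xb),
               welch_t = w$t, df = w$df, p = w$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$bh_q <- NA_real_
  for (m in unique(out$metabolite)) {
    i <- out$metabolite == m
    out$bh_q[i] <- stats::p.adjust(out$p[i], method = "BH")
  }
  out <- out[order(out$metabolite, out$mass_shift), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.welch <- function(xa, xb) {
  na <- length(xa)
  nb <- length(xb)
  va <- stats::var(xa) / na
  vb <- stats::var(xb) / nb
  if (va + vb == 0) {
    eq <- isTRUE(all.equal(mean(xa), mean(xb)))
    return(list(t = if (eq) 0 else Inf, df = na + nb - 2,
                p = if (eq) 1 else 0))
  }
  t <- (mean(xa) - mean(xb)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}
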