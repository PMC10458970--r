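#' Specific activity
#'
#' Activity per unit mass of the element, in TBq/mg as customarily quoted
#' for radiometal products.
#'
#' @param activity Activity in MBq.
#' @param mass Elemental mass in mg (> 0).
#' @return Specific activity in TBq/mg.
#' @export
specific_activity <- function(activity, mass) {
  check_scalar_number(activity, "activity", nonneg = TRUE)
  check_scalar_number(mass, "mass", positive = TRUE)
  (activity * 1e-6) / mass   # MBq -> TBq
}

#' Carrier-free specific-activity ceiling
#'
#' The theoretical maximum specific activity of a radionuclide free of
#' stable isotopes of the same element: `lambda * N_A / M`, expressed in
#' TBq/mg. Any measured specific activity must lie at or below this value.
#'
#' @param n A radioactive [nuclide].
#' @return Ceiling in TBq/mg.
#' @examples
#' sc47 <- nuclide("Sc-47", 47, 46.9524, half_life = 3.3492 * 86400)
#' max_specific_activity(sc47)   # ~30.7 TBq/mg, above the ~26 TBq/mg seen in practice
#' @export
max_specific_activity <- function(n) {
  stopifnot(inherits(n, "nuclide"))
  if (!is_radioactive(n))
    abort_validation(sprintf("'%s' is stable; carrier-free ceiling undefined",
                             n$symbol))
  bq_per_g <- n$decay_constant * AVOGADRO / n$molar_mass
  bq_per_g * 1e-15   # Bq/g -> TBq/mg
}

#' Molar activity
#'
#' Activity per amount of compound, in MBq/nmol as quoted for labeled doses.
#'
#' @param activity Activity in MBq.
#' @param amount Amount in nmol (> 0).
#' @return Molar activity in MBq/nmol.
#' @export
molar_activity <- function(activity, amount) {
  check_scalar_number(activity, "activity", nonneg = TRUE)
  check_scalar_number(amount, "amount", positive = TRUE)
  activity / amount
}

#' Carrier-free molar-activity ceiling
#'
#' `lambda * N_A` per nmol for carrier-free material, in MBq/nmol.
#'
#' @param n A radioactive [nuclide].
#' @return Ceiling in MBq/nmol.
#' @export
max_molar_activity <- function(n) {
  stopifnot(inherits(n, "nuclide"))
  if (!is_radioactive(n))
    abort_validation(sprintf("'%s' is stable; carrier-free ceiling undefined",
                             n$symbol))
  n$decay_constant * AVOGADRO * 1e-9 / 1e6   # Bq/nmol -> MBq/nmol
}

#' Chelator titration series
#'
#' A decade-style DOTA titration: a fixed spike of activity complexed
#' against decreasing chelator amounts, each point reporting the fraction
#' of activity bound. Point order carries no meaning.
#'
#' @param spiked_activity Spiked activity per tube in MBq.
#' @param dota_nmol Chelator amounts in nmol (strictly positive, >= 2 points).
#' @param fraction_bound Bound fractions in `[0, 1]`, same length.
#' @return An object of class `titration_series`.
#' @export
titration_series <- function(spiked_activity, dota_nmol, fraction_bound) {
  check_scalar_number(spiked_activity, "spiked_activity", positive = TRUE)
  if (length(dota_nmol) < 2L)
    abort_validation("titration series needs at least 2 points")
  if (length(fraction_bound) != length(dota_nmol))
    abort_validation("dota_nmol and fraction_bound differ in length")
  if (any(dota_nmol <= 0))
    abort_validation("chelator amounts must be strictly positive")
  if (any(fraction_bound < 0 | fraction_bound > 1))
    abort_validation("fraction_bound must lie in [0, 1]")
  structure(list(spiked_activity = spiked_activity,
                 points = data.frame(dota_nmol = as.numeric(dota_nmol),
                                     fraction_bound = as.numeric(fraction_bound))),
            class = "titration_series")
}

#' Convert a chelator mass to amount
#'
#' Micrograms of DOTA to nmol using the packaged molar mass of 404.42 g/mol.
#'
#' @param ug Mass in micrograms.
#' @return Amount in nmol.
#' @export
dota_ug_to_nmol <- function(ug) ug / DOTA_MOLAR_MASS * 1000

#' Apparent molar activity from a titration series
#'
#' Estimator: the apparent molar activity (AMA) is the spiked activity
#' divided by the smallest chelator amount whose bound fraction reaches the
#' labeling threshold (default 0.90). With a decade-spaced series the
#' estimate is quantised to within one decade of the underlying value. When
#' even the smallest tabulated amount labels above threshold the result is
#' flagged as a lower bound; when no point reaches threshold the AMA is not
#' determined.
#'
#' @param s A [titration_series].
#' @param threshold Bound-fraction threshold defining successful labeling.
#' @return An object of class `ama_estimate` with fields `determined`
#'   (logical), `value` (MBq/nmol or `NA`), `lower_bound` (logical), and
#'   `at_nmol` (the chelator amount used).
#' @export
ama_from_titration <- function(s, threshold = 0.90) {
  stopifnot(inherits(s, "titration_series"))
  if (threshold <= 0 || threshold > 1)
    abort_validation("'threshold' must lie in (0, 1]")
  p <- s$points[order(s$points$dota_nmol), ]
  ok <- p$fraction_bound >= threshold
  if (!any(ok)) {
    return(structure(list(determined = FALSE, value = NA_real_,
                          lower_bound = FALSE, at_nmol = NA_real_,
                          threshold = threshold),
                     class = "ama_estimate"))
  }
  amount <- p$dota_nmol[which(ok)[1]]
  structure(list(determined = TRUE,
                 value = s$spiked_activity / amount,
                 lower_bound = which(ok)[1] == 1L,
                 at_nmol = amount,
                 threshold = threshold),
            class = "ama_estimate")
}

#' @export
print.ama_estimate <- function(x, ...) {
  if (!x$determined) {
    cat("<ama_estimate> not determined (no point reached threshold",
        sprintf("%.2f)\n", x$threshold))
  } else {
    cat(sprintf("<ama_estimate> %s%.4g MBq/nmol (at %.4g nmol, threshold %.2f)\n",
                if (x$lower_bound) ">= " else "", x$value, x$at_nmol,
                x$threshold))
  }
  invisible(x)
}

#' Radio-TLC trace
#'
#' A scanned chromatography lane: count rate sampled along the lane plus
#' labelled integration regions (origin, product, ...). Regions must not
#' overlap; positions must strictly increase.
#'
#' @param position_mm Strictly increasing positions along the lane (mm).
#' @param counts Non-negative counts at each position.
#' @param regions Data frame with columns `label`, `start_mm`, `end_mm`.
#' @return An object of class `tlc_trace`.
#' @export
tlc_trace <- function(position_mm, counts, regions) {
  if (length(position_mm) != length(counts))
    abort_validation("position_mm and counts differ in length")
  if (any(diff(position_mm) <= 0))
    abort_validation("positions must be strictly increasing")
  if (any(counts < 0))
    abort_validation("counts must be non-negative")
  regions <- as.data.frame(regions)
  if (!all(c("label", "start_mm", "end_mm") %in% names(regions)))
    abort_validation("regions needs columns label, start_mm, end_mm")
  if (any(regions$end_mm <= regions$start_mm))
    abort_validation("each region must have end_mm > start_mm")
  r <- regions[order(regions$start_mm), ]
  if (nrow(r) > 1 && any(r$start_mm[-1] < r$end_mm[-nrow(r)]))
    abort_validation("regions must not overlap")
  structure(list(position_mm = as.numeric(position_mm),
                 counts = as.numeric(counts),
                 regions = regions),
            class = "tlc_trace")
}

in_region <- function(pos, start, end) pos >= start & pos <= end

#' Radiochemical labeling yield from a TLC trace
#'
#' Fits a linear baseline through the region-free flanks of the lane,
#' subtracts it, and reports the product region's share of the
#' baseline-subtracted counts summed over all regions — the fraction of
#' activity incorporated into the labeled product.
#'
#' @param trace A [tlc_trace].
#' @param product_region Label of the product region.
#' @return Labeling yield as a fraction in `[0, 1]`.
#' @export
labeling_yield <- function(trace, product_region) {
  stopifnot(inherits(trace, "tlc_trace"))
  if (!product_region %in% trace$regions$label)
    abort_validation(sprintf("no region labelled '%s'", product_region))
  pos <- trace$position_mm
  cts <- trace$counts
  in_any <- Reduce(`|`, lapply(seq_len(nrow(trace$regions)), function(i)
    in_region(pos, trace$regions$start_mm[i], trace$regions$end_mm[i])))
  baseline <- if (sum(!in_any) >= 2) {
    fit <- stats::lm.fit(cbind(1, pos[!in_any]), cts[!in_any])
    cbind(1, pos) %*% fit$coefficients
  } else {
    rep(0, length(pos))
  }
  net <- pmax(cts - as.numeric(baseline), 0)
  region_sum <- function(i) sum(net[in_region(pos, trace$regions$start_mm[i],
                                              trace$regions$end_mm[i])])
  sums <- vapply(seq_len(nrow(trace$regions)), region_sum, numeric(1))
  total <- sum(sums)
  if (total <= 0)
    abort_validation("no counts above baseline in any region")
  sums[match(product_region, trace$regions$label)] / total
}
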