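#' Expression inference from binned sort-seq counts
#'
#' Reads observed per bin are first reweighted to reflect cells sorted, then
#' each variant's bin profile is fit to a gamma distribution by maximizing
#' the interval-censored likelihood; the inferred expression is the fitted
#' gamma mean k*theta.
#'
#' @name binfit
NULL

#' Depth-normalize a sort-seq count matrix
#'
#' Reads in bin b are scaled by `cell_fraction[b] / total_reads[b]` so that
#' a read stands for a fixed number of sorted cells regardless of how deeply
#' its bin was sequenced; each variant's vector is then rescaled to preserve
#' its raw read total. A bin with zero reads but a nonzero cell fraction
#' gets weight 0 with a warning.
#'
#' @param cm A `count_matrix` (see [simulate_counts()] / [read_counts()])
#'   whose schema has `cell_fraction` populated.
#' @return A `count_matrix` with numeric weighted counts.
#' @export
normalize_counts <- function(cm) {
  counts <- cm$counts
  cf <- cm$schema$cell_fraction
  if (anyNA(cf)) stop("schema cell_fraction is not populated", call. = FALSE)
  totals <- colSums(counts)
  w <- ifelse(totals > 0, cf / totals, 0)
  if (any(totals == 0 & cf > 0)) {
    warning("bin(s) with zero total reads but nonzero cell fraction; weight set to 0")
  }
  weighted <- sweep(counts, 2L, w, `*`)
  rs_raw <- rowSums(counts)
  rs_new <- rowSums(weighted)
  scale <- ifelse(rs_new > 0, rs_raw / rs_new, 0)
  out <- cm
  out$counts <- weighted * scale
  out
}

# Representative per-bin expression values for moment starts and fallbacks:
# geometric midpoints of interior bins, geometric extrapolation for the
# open outer bins.
bin_midpoints <- function(schema) {
  b <- schema$boundaries
  nb <- schema$n_bins
  mids <- sqrt(b[-(nb + 1)] * b[-1])
  ratio <- b[3] / b[2]
  mids[1] <- b[2] / sqrt(ratio)
  mids[nb] <- b[nb] * sqrt(ratio)
  mids
}

#' Fit a gamma distribution to one variant's binned reads
#'
#' Maximizes the interval-censored log-likelihood
#' `sum_b n_b log(F(u_b; k, theta) - F(l_b; k, theta))` over
#' `(log k, log theta)` (F the gamma CDF, bins `(l_b, u_b]` with open outer
#' bins) using BFGS from a moment-based start plus two perturbed restarts.
#' The inferred expression is the gamma mean `k * theta`.
#'
#' @param counts Numeric vector of (possibly weighted) reads per bin.
#' @param schema A [bin_schema()].
#' @param min_reads Minimum weighted read total for an ML fit; below it the
#'   midpoint-weighted mean is returned with status `insufficient_reads`.
#' @param variant_id Identifier carried into the result.
#' @return One-row tibble: `variant_id, mean_au, gamma_shape, gamma_scale,
#'   loglik, n_reads, status` (`ml_fit`, `fallback_midpoint`, or
#'   `insufficient_reads`).
#' @export
fit_gamma_binned <- function(counts, schema, min_reads = 20, variant_id = "v") {
  nb <- schema$n_bins
  stopifnot(length(counts) == nb, all(counts >= 0))
  b <- schema$boundaries
  total <- sum(counts)
  mids <- bin_midpoints(schema)
  mid_mean <- if (total > 0) sum(counts * mids) / total else NA_real_
  res <- function(mean_au, shape, scale, loglik, status) {
    tibble::tibble(variant_id = variant_id, mean_au = mean_au,
                   gamma_shape = shape, gamma_scale = scale,
                   loglik = loglik, n_reads = total, status = status)
  }
  if (total < min_reads) {
    return(res(mid_mean, NA_real_, NA_real_, NA_real_, "insufficient_reads"))
  }
  occ <- counts > 0
  negll <- function(par) {
    if (any(!is.finite(par)) || any(abs(par) > 30)) return(1e10)
    k <- exp(par[1]); th <- exp(par[2])
    p <- pgamma(b[-1], shape = k, scale = th) -
         pgamma(b[-(nb + 1)], shape = k, scale = th)
    p <- pmax(p[occ], 1e-300)
    v <- -sum(counts[occ] * log(p))
    if (!is.finite(v)) 1e10 else v
  }
  m1 <- mid_mean
  m2 <- sum(counts * mids^2) / total
  v <- max(m2 - m1^2, (0.05 * m1)^2)
  k0 <- max(min(m1^2 / v, 500), 0.05)
  th0 <- m1 / k0
  starts <- list(c(log(k0), log(th0)),
                 c(log(k0) + 0.7, log(th0) - 0.7),
                 c(log(k0) - 0.7, log(th0) + 0.7))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      optim(s, negll, method = "BFGS",
            control = list(reltol = 1e-10, maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best) || !is.finite(best$value)) {
    return(res(mid_mean, NA_real_, NA_real_, NA_real_, "fallback_midpoint"))
  }
  k <- exp(best$par[1]); th <- exp(best$par[2])
  res(k * th, k, th, -best$value, "ml_fit")
}

#' Fit every variant in a count matrix
#'
#' @param cm A `count_matrix`, typically after [normalize_counts()].
#' @param min_reads Passed to [fit_gamma_binned()].
#' @return Tibble of per-variant estimates.
#' @export
fit_library <- function(cm, min_reads = 20) {
  ids <- rownames(cm$counts)
  purrr::map_dfr(seq_along(ids), function(i) {
    fit_gamma_binned(cm$counts[i, ], cm$schema, min_reads = min_reads,
                     variant_id = ids[i])
  })
}

#' Technical noise from barcode-replicate groups
#'
#' Groups of strains carrying the same variable region under different
#' barcodes should measure identically; their spread is the platform's
#' technical noise. Per group the relative standard deviation
#' (RSD = sd/mean of member `mean_au`) is computed and the median over
#' groups reported.
#'
#' @param estimates Tibble from [fit_library()].
#' @param groups Tibble `variant_id, group_id` mapping members to groups.
#' @param min_size Minimum usable members per retained group (default 10).
#' @return List with `per_group` (tibble `group_id, n, rsd`) and
#'   `median_rsd` (fraction, not percent).
#' @export
median_technical_rsd <- function(estimates, groups, min_size = 10) {
  d <- dplyr::inner_join(estimates, groups, by = "variant_id")
  d <- dplyr::filter(d, is.finite(.data$mean_au), .data$mean_au > 0,
                     !is.na(.data$group_id))
  per_group <- d |>
    dplyr::group_by(.data$group_id) |>
    dplyr::summarise(n = dplyr::n(),
                     rsd = sd(.data$mean_au) / mean(.data$mean_au),
                     .groups = "drop") |>
    dplyr::filter(.data$n >= min_size)
  if (nrow(per_group) == 0) {
    stop("no barcode group with at least ", min_size, " usable members",
         call. = FALSE)
  }
  list(per_group = per_group, median_rsd = median(per_group$rsd))
}
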