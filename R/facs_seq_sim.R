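#' Synthetic sort-seq data generation
#'
#' The simulator plays the role of the wet-lab measurement: it assigns each
#' designed variant a ground-truth mean expression (arbitrary units, a.u.)
#' driven by the TA-dinucleotide content of a planted efficiency element and
#' the A/T content of its flanks, then sorts gamma-distributed single-cell
#' expression values into 16 FACS bins and draws sequencing reads per bin.
#' Because the truth is known, every downstream inference stage can be
#' validated against it.
#'
#' @name facs_seq_sim
NULL

#' Ground-truth expression parameters
#'
#' @param low_mode Expression of variants with a fully disrupted element
#'   (a.u.; the low peak of the bimodal library distribution sits below 1).
#' @param high_max Expression ceiling for a consensus-strength element (a.u.).
#' @param ta_gain Logistic slope per overlapping TA dinucleotide inside the
#'   element interval.
#' @param context_at_weight Logistic weight on the A/T fraction of the
#'   sequence flanking the element.
#' @param logistic_offset Logistic intercept; with the default gain this
#'   places a TA-free element deep in the low mode.
#' @param strain_noise_sd Log-scale standard deviation of the multiplicative
#'   strain-to-strain (technical) noise; 0.13 reproduces a median barcode
#'   replicate relative standard deviation of ~13%.
#' @param seed Integer seed anchoring per-variant noise draws.
#' @return A `truth_params` list.
#' @export
truth_params <- function(low_mode = 0.5, high_max = 10, ta_gain = 3.6,
                         context_at_weight = 2, logistic_offset = 12.2,
                         strain_noise_sd = 0.13, seed = 1L) {
  stopifnot(low_mode < high_max, strain_noise_sd >= 0)
  structure(list(low_mode = low_mode, high_max = high_max, ta_gain = ta_gain,
                 context_at_weight = context_at_weight,
                 logistic_offset = logistic_offset,
                 strain_noise_sd = strain_noise_sd, seed = as.integer(seed)),
            class = "truth_params")
}

#' Ground-truth mean expression of one variant
#'
#' The noiseless mean is
#' `low_mode + (high_max - low_mode) * plogis(ta_gain * nTA + context_at_weight * fAT - offset)`
#' where `nTA` counts overlapping TA dinucleotides inside the parent's
#' element interval and `fAT` is the A/T fraction of the sequence outside
#' it. A log-normal strain factor (sd `strain_noise_sd`) multiplies the
#' mean; it is a deterministic function of `(params$seed, variant_id)`, so
#' the same variant always receives the same draw regardless of processing
#' order.
#'
#' @param variable_region Variant sequence.
#' @param element_start,element_end The parent's element interval (0-based,
#'   half-open) within the variable region.
#' @param params A [truth_params()] object.
#' @param variant_id Identifier used to derive the strain noise draw.
#' @param noiseless If TRUE, return the mean without the strain factor.
#' @return Expression in a.u. (positive scalar).
#' @export
truth_expression <- function(variable_region, element_start, element_end,
                             params = truth_params(), variant_id = "v",
                             noiseless = FALSE) {
  element <- subseq0(variable_region, element_start, element_end)
  flanks <- paste0(subseq0(variable_region, 0, element_start),
                   subseq0(variable_region, element_end, nchar(variable_region)))
  n_ta <- count_kmer(element, "TA")
  f_at <- at_fraction(flanks)
  if (is.na(f_at)) f_at <- 0.5
  s <- plogis(params$ta_gain * n_ta + params$context_at_weight * f_at -
                params$logistic_offset)
  mu <- params$low_mode + (params$high_max - params$low_mode) * s
  if (noiseless || params$strain_noise_sd == 0) return(mu)
  h <- (as.numeric(string_hash(variant_id)) +
          as.numeric(params$seed) * 7919) %% 2147483629
  z <- with_local_seed(h, rnorm(1))
  mu * exp(params$strain_noise_sd * z - params$strain_noise_sd^2 / 2)
}

#' 16-bin FACS sorting schema
#'
#' Bin boundaries on the expression axis. The default gating is log-uniform
#' between `min_au` and `max_au` with open outer bins `(0, b1]` and
#' `(b_{n-1}, Inf)`; `"equal_count"` gating instead places boundaries at
#' quantiles of a reference expression sample.
#'
#' @param n_bins Number of bins (default 16).
#' @param min_au,max_au Interior boundary range for log-uniform gating (a.u.).
#' @param gating `"log_uniform"` or `"equal_count"`.
#' @param reference Numeric expression sample required for equal-count gating.
#' @return A `bin_schema` list with `boundaries` (length `n_bins + 1`,
#'   first 0, last `Inf`) and an empty `cell_fraction` slot filled by
#'   [simulate_counts()].
#' @export
bin_schema <- function(n_bins = 16L, min_au = 0.2, max_au = 20,
                       gating = c("log_uniform", "equal_count"),
                       reference = NULL) {
  gating <- match.arg(gating)
  stopifnot(n_bins >= 2, min_au > 0, max_au > min_au)
  interior <- switch(gating,
    log_uniform = exp(seq(log(min_au), log(max_au), length.out = n_bins - 1L)),
    equal_count = {
      if (is.null(reference)) stop("equal_count gating needs a reference sample")
      unname(quantile(reference, probs = seq_len(n_bins - 1L) / n_bins))
    }
  )
  boundaries <- c(0, interior, Inf)
  if (is.unsorted(boundaries, strictly = TRUE)) {
    stop("bin boundaries are not strictly increasing")
  }
  structure(list(n_bins = as.integer(n_bins), boundaries = boundaries,
                 cell_fraction = rep(NA_real_, n_bins), gating = gating),
            class = "bin_schema")
}

#' Simulate a sort-seq count matrix
#'
#' Per variant, `n_cells` single-cell expression values are drawn from a
#' gamma distribution with shape `k_cell` and the variant's true mean
#' (`cell_model = "lognormal"` substitutes a log-normal with matched mean
#' and CV, a deliberate model misspecification switch); each cell falls into
#' the bin containing its value, and reads per bin are Poisson with
#' expectation `cells in bin x reads_per_cell`.
#'
#' @param means Named numeric vector of true mean expressions (a.u.),
#'   names = variant ids.
#' @param schema A [bin_schema()].
#' @param n_cells Sorted cells per variant.
#' @param reads_per_cell Expected sequencing reads per sorted cell.
#' @param k_cell Gamma shape of cell-to-cell expression variability.
#' @param cell_model `"gamma"` (matched to the inference model) or
#'   `"lognormal"` (misspecified).
#' @return A `count_matrix` list: integer `counts` (variants x bins),
#'   `schema` with `cell_fraction` populated, and `cell_totals` per bin.
#' @export
simulate_counts <- function(means, schema, n_cells = 2000L, reads_per_cell = 0.25,
                            k_cell = 25, cell_model = c("gamma", "lognormal")) {
  cell_model <- match.arg(cell_model)
  if (any(means <= 0)) stop("all true means must be positive", call. = FALSE)
  stopifnot(k_cell > 0, n_cells >= 0, reads_per_cell >= 0)
  nb <- schema$n_bins
  counts <- matrix(0L, nrow = length(means), ncol = nb,
                   dimnames = list(names(means), paste0("bin_", seq_len(nb))))
  cell_totals <- numeric(nb)
  cv <- 1 / sqrt(k_cell)
  for (i in seq_along(means)) {
    if (n_cells == 0) next
    x <- if (cell_model == "gamma") {
      rgamma(n_cells, shape = k_cell, scale = means[i] / k_cell)
    } else {
      sdlog <- sqrt(log1p(cv^2))
      stats::rlnorm(n_cells, meanlog = log(means[i]) - sdlog^2 / 2, sdlog = sdlog)
    }
    cells_in_bin <- tabulate(findInterval(x, schema$boundaries,
                                          rightmost.closed = FALSE), nbins = nb)
    cell_totals <- cell_totals + cells_in_bin
    counts[i, ] <- rpois(nb, cells_in_bin * reads_per_cell)
  }
  schema$cell_fraction <- if (sum(cell_totals) > 0) cell_totals / sum(cell_totals)
                          else rep(0, nb)
  structure(list(counts = counts, schema = schema, cell_totals = cell_totals),
            class = "count_matrix")
}

#' Default synthetic-library configuration
#'
#' Defines the study conditions the simulator emulates: number of native
#' parents, the scanning scheme, a planted 10 bp TA-rich efficiency element
#' whose center lies 40 bp upstream of the designated main polyadenylation
#' site, element strengths spanning 3-5 TA dinucleotides, and barcode
#' replicate groups for technical-noise estimation.
#'
#' @param n_native Number of native-like parent sequences.
#' @param schemes Character subset of `c("scan10", "scan9")`.
#' @param scan9_fraction Fraction of parents additionally mutated with the
#'   fine 9 bp / 3 bp-step scheme when `"scan9"` is configured; the fine
#'   scheme's windows straddle the element boundary and probe partial
#'   disruptions.
#' @param region_length Variable-region length (bp).
#' @param background_at A/T fraction of the random background sequence;
#'   yeast 3' end regions are A/T-rich, and background TA-dinucleotide
#'   decoys are what the element model must discriminate against.
#' @param polya_pos Designated main polyA site (0-based position).
#' @param element_length Planted element length (bp).
#' @param element_offset Distance from element center to the polyA site (bp,
#'   element upstream).
#' @param ta_range Integer range of TA-dinucleotide copies across parents.
#' @param n_rsd_groups Number of parents replicated as barcode groups.
#' @param rsd_group_size Barcode replicates per group.
#' @param n_cells,reads_per_cell,k_cell Passed to [simulate_counts()].
#' @param truth A [truth_params()] object.
#' @return A named list of configuration values.
#' @export
library_config <- function(n_native = 50L, schemes = c("scan10", "scan9"),
                           scan9_fraction = 0.15,
                           region_length = 102L, background_at = 0.52,
                           polya_pos = 85L,
                           element_length = 10L, element_offset = 40L,
                           ta_range = c(3L, 5L), n_rsd_groups = 0L,
                           rsd_group_size = 10L, n_cells = 2000L,
                           reads_per_cell = 0.25, k_cell = 25,
                           truth = truth_params()) {
  stopifnot(all(schemes %in% c("scan10", "scan9")),
            element_length %% 2L == 0L,
            polya_pos <= region_length,
            n_rsd_groups <= max(n_native, 1L))
  el_start <- polya_pos - element_offset - element_length %/% 2L
  if (el_start < 0 || el_start + element_length > region_length) {
    stop("planted element falls outside the variable region", call. = FALSE)
  }
  stopifnot(background_at > 0, background_at < 1)
  list(n_native = as.integer(n_native), schemes = schemes,
       scan9_fraction = scan9_fraction,
       region_length = as.integer(region_length),
       background_at = background_at,
       polya_pos = as.integer(polya_pos),
       element_length = as.integer(element_length),
       element_offset = as.integer(element_offset),
       element_start = as.integer(el_start),
       ta_range = as.integer(ta_range), n_rsd_groups = as.integer(n_rsd_groups),
       rsd_group_size = as.integer(rsd_group_size),
       n_cells = as.integer(n_cells), reads_per_cell = reads_per_cell,
       k_cell = k_cell, truth = truth)
}

# Planted element: s tandem TA copies completed to `length` by filler drawn
# from the background base composition, except that an A is never placed
# right after a T. The overlapping TA-dinucleotide count inside the element
# therefore equals s exactly, while the filler stays as heterogeneous as
# the surrounding sequence (so nothing but TA content marks the element).
planted_element <- function(length, n_ta, background_at = 0.52) {
  stopifnot(2 * n_ta <= length)
  p_at <- background_at / 2
  prob <- c(p_at, 0.5 - p_at, 0.5 - p_at, p_at)
  out <- strsplit(strrep("TA", n_ta), "")[[1]]
  for (i in seq_len(length - 2 * n_ta)) {
    prev <- out[base::length(out)]
    keep <- if (identical(prev, "T")) 2:4 else 1:4
    out <- c(out, sample(DNA_BASES[keep], 1, prob = prob[keep]))
  }
  paste(out, collapse = "")
}

# Remove TA dinucleotides inside [start, end) by rewriting the A of each
# occurrence to C or G. One left-to-right pass suffices: deleting an A can
# never create a new TA. Used to keep the planted element's immediate
# neighborhood TA-free, so each parent carries a single TA-rich feature at
# the polyA-proximal position (the single-element regime the scanning
# parents are selected for); distal TA decoys are left untouched.
scrub_ta <- function(seq, start, end) {
  ch <- strsplit(seq, "")[[1]]
  for (p in seq.int(max(start, 1L), min(end, length(ch) - 1L))) {
    if (ch[p] == "T" && ch[p + 1L] == "A") {
      ch[p + 1L] <- sample(c("C", "G"), 1)
    }
  }
  paste(ch, collapse = "")
}

#' Generate a full synthetic library with ground truth and counts
#'
#' Builds native parents with planted efficiency elements, applies the
#' configured scanning schemes, adds barcode-replicate groups, computes
#' ground-truth expression for every variant from its own sequence (so a
#' scanning mutation that destroys the element collapses its truth to the
#' low mode), and simulates the sort-seq count matrix.
#'
#' @param config A [library_config()].
#' @param seed Integer seed; the whole library is a deterministic function
#'   of `(config, seed)`.
#' @return A list with `manifest` (tibble; extra columns `true_mean`,
#'   `group_id`), `truth` (the `truth_params` used, seed overridden to
#'   `seed`), `counts` (a `count_matrix`), `polya` (tibble
#'   `parent_id, main_site`), and `elements` (tibble
#'   `parent_id, element_start, element_end, n_ta`).
#' @export
generate_library <- function(config = library_config(), seed = 1L) {
  set.seed(seed)
  config$truth$seed <- as.integer(seed)
  if (config$n_native == 0) {
    empty <- new_variant_row(character(0), character(0), character(0),
                             variable_region = character(0))[0, ]
    return(list(manifest = empty, truth = config$truth,
                counts = NULL,
                polya = tibble::tibble(parent_id = character(0), main_site = integer(0)),
                elements = tibble::tibble(parent_id = character(0),
                                          element_start = integer(0),
                                          element_end = integer(0), n_ta = integer(0))))
  }
  el_s <- config$element_start
  el_e <- el_s + config$element_length
  parents <- purrr::map_dfr(seq_len(config$n_native), function(i) {
    pid <- sprintf("native%03d", i)
    n_ta <- sample(seq(config$ta_range[1], config$ta_range[2]), 1L)
    p_at <- config$background_at / 2
    bg <- random_dna(config$region_length,
                     prob = c(p_at, 0.5 - p_at, 0.5 - p_at, p_at))
    seqv <- replace_at0(bg, el_s,
                        planted_element(config$element_length, n_ta,
                                        config$background_at))
    seqv <- scrub_ta(seqv, el_s - 15L, el_s)
    seqv <- scrub_ta(seqv, el_e, el_e + 15L)
    row <- new_variant_row(variant_id = paste0(pid, "_wt"), parent_id = pid,
                           category = "native_wt", variable_region = seqv)
    row$n_ta <- n_ta
    row
  })
  elements <- tibble::tibble(parent_id = parents$parent_id,
                             element_start = el_s, element_end = el_e,
                             n_ta = parents$n_ta)
  polya <- tibble::tibble(parent_id = parents$parent_id,
                          main_site = config$polya_pos)
  scan9_set <- if ("scan9" %in% config$schemes) {
    seq_len(max(0L, round(config$scan9_fraction * nrow(parents))))
  } else integer(0)
  mutants <- purrr::map_dfr(seq_len(nrow(parents)), function(i) {
    p <- parents[i, c("variant_id", "parent_id", "category", "window_start",
                      "window_end", "replicate_index", "barcode", "variable_region")]
    dplyr::bind_rows(
      if ("scan10" %in% config$schemes) scan_library_10bp(p),
      if (i %in% scan9_set) scan_library_9bp(p)
    )
  })
  # barcode-replicate groups: extra copies of the first n_rsd_groups parents,
  # identical sequence, distinct barcode, independent strain noise
  rsd <- if (config$n_rsd_groups > 0) {
    purrr::map_dfr(seq_len(config$n_rsd_groups), function(i) {
      purrr::map_dfr(seq_len(config$rsd_group_size), function(r) {
        row <- new_variant_row(
          variant_id = sprintf("%s_bcrep%02d", parents$parent_id[i], r),
          parent_id = parents$parent_id[i], category = "native_wt",
          replicate_index = r, variable_region = parents$variable_region[i])
        row$group_id <- parents$parent_id[i]
        row
      })
    })
  } else NULL
  manifest <- dplyr::bind_rows(
    dplyr::select(parents, -"n_ta"), mutants, rsd
  )
  if (!"group_id" %in% names(manifest)) manifest$group_id <- NA_character_
  manifest <- assign_barcodes(manifest)
  manifest$true_mean <- vapply(seq_len(nrow(manifest)), function(i) {
    truth_expression(manifest$variable_region[i], el_s, el_e,
                     params = config$truth, variant_id = manifest$variant_id[i])
  }, numeric(1))
  schema <- bin_schema()
  means <- setNames(manifest$true_mean, manifest$variant_id)
  counts <- simulate_counts(means, schema, n_cells = config$n_cells,
                            reads_per_cell = config$reads_per_cell,
                            k_cell = config$k_cell)
  list(manifest = manifest, truth = config$truth, counts = counts,
       polya = polya, elements = elements)
}
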