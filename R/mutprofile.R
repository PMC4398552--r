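#' Mutation-effect profiles and element calling
#'
#' Scanning-mutagenesis estimates are turned into per-window log2
#' fold-change profiles against the parent wild type; runs of windows whose
#' mutants collapse below an absolute expression threshold are merged into
#' the called functional element; and positions of maximal effect are
#' related to the annotated main polyadenylation site.
#'
#' @name mutprofile
NULL

#' Per-window fold-change profile for one parent
#'
#' For each designed window, the ratio between the mean expression of the
#' replicate mutants and the un-mutated wild type is computed; its log2 is
#' the window's effect.
#'
#' @param manifest Manifest tibble covering the parent's wild type and its
#'   scanning mutants (categories `scan10`/`scan9`).
#' @param estimates Estimates tibble from [fit_library()].
#' @param parent_id Parent to profile.
#' @return Tibble with one row per window: `parent_id, window_start,
#'   window_end, rep_means` (list column), `n_reps, mean_mut_au, wt_au,
#'   ratio, log2fc`.
#' @export
fold_change_profile <- function(manifest, estimates, parent_id) {
  pid <- parent_id
  if (!"group_id" %in% names(manifest)) manifest$group_id <- NA_character_
  wt_row <- manifest |>
    dplyr::filter(.data$parent_id == pid, .data$category == "native_wt") |>
    dplyr::arrange(!is.na(.data$group_id))
  if (nrow(wt_row) == 0) stop("no wild type found for parent ", pid, call. = FALSE)
  wt_est <- dplyr::filter(estimates, .data$variant_id == wt_row$variant_id[1])
  if (nrow(wt_est) == 0 || !is.finite(wt_est$mean_au) || wt_est$mean_au <= 0) {
    stop("wild-type expression unavailable or nonpositive for parent ", pid,
         call. = FALSE)
  }
  muts <- manifest |>
    dplyr::filter(.data$parent_id == pid, .data$category %in% c("scan10", "scan9")) |>
    dplyr::inner_join(estimates, by = "variant_id")
  muts |>
    dplyr::group_by(.data$window_start, .data$window_end) |>
    dplyr::summarise(rep_means = list(.data$mean_au), n_reps = dplyr::n(),
                     mean_mut_au = mean(.data$mean_au), .groups = "drop") |>
    dplyr::mutate(parent_id = pid, wt_au = wt_est$mean_au[1],
                  ratio = .data$mean_mut_au / .data$wt_au,
                  log2fc = log2(.data$ratio)) |>
    dplyr::arrange(.data$window_start) |>
    dplyr::select("parent_id", dplyr::everything())
}

#' Profiles for all parents in a manifest
#' @inheritParams fold_change_profile
#' @return Row-bound profile tibble across parents.
#' @export
fold_change_profiles <- function(manifest, estimates) {
  parents <- unique(manifest$parent_id[manifest$category %in% c("scan10", "scan9")])
  purrr::map_dfr(parents, function(p) {
    tryCatch(fold_change_profile(manifest, estimates, p),
             error = function(e) {
               warning("skipping parent ", p, ": ", conditionMessage(e))
               NULL
             })
  })
}

#' Fractions of windows changing expression more than a given fold
#'
#' @param profiles Profile tibble from [fold_change_profiles()].
#' @param fold Fold-change cutoff (default 2).
#' @return Named list `fraction_decrease` (ratio <= 1/fold) and
#'   `fraction_increase` (ratio >= fold), over all window entries.
#' @export
effect_fractions <- function(profiles, fold = 2) {
  stopifnot(nrow(profiles) > 0, fold > 1)
  r <- profiles$ratio[is.finite(profiles$ratio)]
  list(fraction_decrease = mean(r <= 1 / fold),
       fraction_increase = mean(r >= fold))
}

#' Consistency between independent mutations of the same window
#'
#' Two different random replacements of the same window should measure
#' alike if the effect comes from the sequence removed rather than the
#' sequence introduced. Computes the Pearson R^2 between replicate 1 and
#' replicate 2 expression across all windows with both replicates.
#'
#' @param profiles Profile tibble (scan10 windows carry two replicates).
#' @return List `n_pairs`, `r_squared`.
#' @export
replicate_consistency <- function(profiles) {
  both <- dplyr::filter(profiles, .data$n_reps >= 2)
  if (nrow(both) < 3) stop("fewer than 3 replicate pairs", call. = FALSE)
  r1 <- vapply(both$rep_means, function(v) v[1], numeric(1))
  r2 <- vapply(both$rep_means, function(v) v[2], numeric(1))
  keep <- is.finite(r1) & is.finite(r2)
  list(n_pairs = sum(keep), r_squared = cor(r1[keep], r2[keep])^2)
}

merge_runs <- function(starts, ends, max_gap = 0L) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1]; me <- ends[1]
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(starts)[-1]) {
    if (starts[i] - me <= max_gap) {
      me <- max(me, ends[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- starts[i]; me <- ends[i]
    }
  }
  tibble::tibble(start = c(out_s, ms), end = c(out_e, me))
}

#' Call the functional element of one parent
#'
#' Windows whose mean mutant expression falls below `abs_threshold`
#' (mutants collapse to a fixed low range, so an absolute cutoff is used
#' rather than fold change) are marked affecting; adjacent affecting
#' windows (gap <= `max_gap` bp) are merged, and the merged run containing
#' the minimum mutant expression is the called element.
#'
#' @param profile Profile tibble for a single parent.
#' @param abs_threshold Absolute expression threshold in a.u. (default 0.8).
#' @param max_gap Maximum gap in bp between merged windows (default 0).
#' @return One-row tibble `parent_id, element_start, element_end,
#'   min_mut_au, n_affecting_windows, is_single_element`, or a zero-row
#'   tibble when no window passes the threshold.
#' @export
call_elements <- function(profile, abs_threshold = 0.8, max_gap = 0L) {
  stopifnot(nrow(profile) > 0, length(unique(profile$parent_id)) == 1)
  empty <- tibble::tibble(parent_id = character(0), element_start = integer(0),
                          element_end = integer(0), min_mut_au = numeric(0),
                          n_affecting_windows = integer(0),
                          is_single_element = logical(0))
  aff <- dplyr::filter(profile, .data$mean_mut_au < abs_threshold)
  if (nrow(aff) == 0) return(empty)
  runs <- merge_runs(aff$window_start, aff$window_end, max_gap = max_gap)
  argmin <- aff$window_start[which.min(aff$mean_mut_au)]
  hit <- which(runs$start <= argmin & argmin < runs$end)
  tibble::tibble(parent_id = profile$parent_id[1],
                 element_start = runs$start[hit], element_end = runs$end[hit],
                 min_mut_au = min(aff$mean_mut_au),
                 n_affecting_windows = sum(aff$window_start >= runs$start[hit] &
                                             aff$window_end <= runs$end[hit]),
                 is_single_element = nrow(runs) == 1)
}

#' Element calls for all parents
#' @param profiles Profile tibble across parents.
#' @inheritParams call_elements
#' @return Row-bound element-call tibble (parents without an element absent).
#' @export
call_elements_all <- function(profiles, abs_threshold = 0.8, max_gap = 0L) {
  profiles |>
    dplyr::group_split(.data$parent_id) |>
    purrr::map_dfr(call_elements, abs_threshold = abs_threshold, max_gap = max_gap)
}

#' Mutation effects relative to the main polyadenylation site
#'
#' Splits window effects by whether the window center lies upstream (5') or
#' downstream of the annotated main polyA site and compares the two log2
#' fold-change samples with a Welch two-sample t-test; also returns, per
#' parent, the signed distance from the maximal-effect window center to the
#' main site (positive = element upstream of the site).
#'
#' @param profiles Profile tibble.
#' @param polya Tibble `parent_id, main_site` (0-based).
#' @return List: `t_stat, p_value, n_upstream, n_downstream, distances`
#'   (tibble `parent_id, distance`), `modal_distance`.
#' @export
polyA_relative_stats <- function(profiles, polya) {
  d <- dplyr::inner_join(profiles, polya, by = "parent_id")
  missing <- setdiff(unique(profiles$parent_id), unique(polya$parent_id))
  if (length(missing) > 0) {
    warning("no polyA annotation for ", length(missing), " parent(s); excluded")
  }
  d$center <- (d$window_start + d$window_end) / 2
  up <- d$log2fc[d$center < d$main_site]
  down <- d$log2fc[d$center >= d$main_site]
  tt <- t.test(up, down, var.equal = FALSE)
  distances <- d |>
    dplyr::group_by(.data$parent_id) |>
    dplyr::slice_min(.data$mean_mut_au, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::transmute(parent_id = .data$parent_id,
                     distance = .data$main_site - .data$center)
  tab <- table(distances$distance)
  modal <- as.numeric(names(tab)[which.max(tab)])
  list(t_stat = unname(tt$statistic), p_value = tt$p.value,
       n_upstream = length(up), n_downstream = length(down),
       distances = distances, modal_distance = modal)
}

#' Permutation test of co-occurrence between effect positions and motif sites
#'
#' The statistic is the mean, over parents, of the minimal distance between
#' the parent's maximal-effect position and its motif sites. The null is
#' built by redrawing each parent's site positions uniformly within its
#' sequence, preserving per-parent site counts; the add-one permutation
#' p-value `(1 + #{perm <= obs}) / (n_perm + 1)` tests whether sites lie
#' closer to effect positions than chance.
#'
#' @param centers Tibble `parent_id, center, seq_length`.
#' @param sites Tibble `parent_id, position` (possibly several per parent).
#' @param n_perm Number of permutations (default 10000).
#' @return List `observed, p_value, n_parents, n_perm`.
#' @export
motif_cooccurrence_test <- function(centers, sites, n_perm = 10000L) {
  stopifnot(n_perm >= 1)
  per_parent <- dplyr::inner_join(
    centers, tidyr::nest(sites, site_positions = "position"),
    by = "parent_id")
  if (nrow(per_parent) == 0) stop("no parent with both a center and sites",
                                  call. = FALSE)
  obs <- vapply(seq_len(nrow(per_parent)), function(i) {
    min(abs(per_parent$center[i] - per_parent$site_positions[[i]]$position))
  }, numeric(1))
  observed <- mean(obs)
  k <- vapply(per_parent$site_positions, nrow, integer(1))
  perm_stats <- vapply(seq_len(n_perm), function(p) {
    mean(vapply(seq_len(nrow(per_parent)), function(i) {
      pos <- runif(k[i], 0, per_parent$seq_length[i])
      min(abs(per_parent$center[i] - pos))
    }, numeric(1)))
  }, numeric(1))
  p <- (1 + sum(perm_stats <= observed)) / (n_perm + 1)
  list(observed = observed, p_value = p, n_parents = nrow(per_parent),
       n_perm = as.integer(n_perm))
}

#' Nucleotide-composition profiles aligned at the main polyA site
#'
#' For each k-mer, computes the per-position coverage indicator (position
#' covered by at least one, possibly overlapping, occurrence), smooths it
#' with a centered sliding window, and averages across sequences at each
#' offset relative to the main polyA site.
#'
#' @param sequences Named character vector of sequences (names = parent ids).
#' @param polya Tibble `parent_id, main_site`.
#' @param kmers Character vector of k-mers (e.g. `c("TA", "T", "A")`).
#' @param window Sliding-window width in bp (default 20).
#' @return Tibble `offset, kmer, frequency` spanning the union of aligned
#'   coordinates.
#' @export
composition_profile <- function(sequences, polya, kmers = c("TA", "T", "A"),
                                window = 20L) {
  ids <- intersect(names(sequences), polya$parent_id)
  stopifnot(length(ids) > 0)
  main <- setNames(polya$main_site, polya$parent_id)[ids]
  purrr::map_dfr(kmers, function(km) {
    k <- nchar(km)
    per_seq <- purrr::map(ids, function(id) {
      s <- sequences[[id]]
      n <- nchar(s)
      covered <- logical(n)
      if (n >= k) {
        starts <- 1:(n - k + 1)
        occ <- which(substring(s, starts, starts + k - 1L) == km)
        for (o in occ) covered[o:(o + k - 1L)] <- TRUE
      }
      smooth <- zoo::rollapply(as.numeric(covered), width = window, FUN = mean,
                               partial = TRUE, align = "center")
      tibble::tibble(offset = (seq_len(n) - 1L) - main[[id]], value = smooth)
    })
    dplyr::bind_rows(per_seq) |>
      dplyr::group_by(.data$offset) |>
      dplyr::summarise(frequency = mean(.data$value), .groups = "drop") |>
      dplyr::mutate(kmer = km) |>
      dplyr::select("offset", "kmer", "frequency")
  })
}
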