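#' Interchange formats and the end-to-end pipeline
#'
#' TSV for manifests, counts, estimates and profiles; FASTA for sequences;
#' BED (0-based half-open) for polyA sites and element calls; JSON for the
#' trained model and the pipeline report. Every writer/reader pair is a
#' round-trip identity on valid data.
#'
#' @name io
NULL

#' @rdname io
#' @param manifest Manifest tibble.
#' @param path Output file path.
#' @export
write_manifest <- function(manifest, path) {
  readr::write_tsv(manifest, path)
  invisible(path)
}

#' @rdname io
#' @export
read_manifest <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           variant_id = "c", parent_id = "c", category = "c",
                           window_start = "i", window_end = "i",
                           replicate_index = "i", barcode = "c",
                           variable_region = "c", .default = readr::col_guess()))
  if ("group_id" %in% names(out)) out$group_id <- as.character(out$group_id)
  out
}

#' @rdname io
#' @export
write_fasta <- function(manifest, path) {
  seqs <- Biostrings::DNAStringSet(setNames(manifest$variable_region,
                                            manifest$variant_id))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @rdname io
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  setNames(as.character(seqs), names(seqs))
}

#' Write / read a sort-seq count matrix as TSV
#'
#' The bin boundaries and cell fractions travel in `#`-prefixed header
#' lines so a count file is self-describing.
#'
#' @param cm A `count_matrix`.
#' @param path File path.
#' @export
write_counts <- function(cm, path) {
  writeLines(c(paste0("# boundaries\t",
                      paste(cm$schema$boundaries, collapse = ",")),
               paste0("# cell_fraction\t",
                      paste(cm$schema$cell_fraction, collapse = ","))), path)
  df <- tibble::as_tibble(cm$counts)
  df <- dplyr::bind_cols(tibble::tibble(variant_id = rownames(cm$counts)), df)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  hdr <- readLines(path, n = 2)
  parse_num <- function(line) as.numeric(strsplit(sub("^# \\w+\t", "", line), ",")[[1]])
  boundaries <- parse_num(hdr[1])
  cell_fraction <- parse_num(hdr[2])
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$variant_id
  nb <- ncol(m)
  schema <- structure(list(n_bins = nb, boundaries = boundaries,
                           cell_fraction = cell_fraction, gating = "file"),
                      class = "bin_schema")
  structure(list(counts = m, schema = schema,
                 cell_totals = rep(NA_real_, nb)), class = "count_matrix")
}

#' @rdname io
#' @param estimates Estimates tibble.
#' @export
write_estimates <- function(estimates, path) {
  readr::write_tsv(estimates, path)
  invisible(path)
}

#' @rdname io
#' @export
read_estimates <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Read polyadenylation-site annotations from BED
#'
#' BED intervals are 0-based half-open; the score column carries the read
#' fraction at the site. Per parent, the main site is the position of
#' maximal fraction, ties broken by the 5'-most position.
#'
#' @param path BED file path.
#' @return List: `sites` (tibble `parent_id, position, fraction`) and
#'   `polya` (tibble `parent_id, main_site, fraction_at_main`).
#' @export
read_polya_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rows <- purrr::map_dfr(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t")[[1]]
    if (length(f) < 5 || is.na(suppressWarnings(as.integer(f[2])))) {
      stop("malformed BED line ", i, ": ", lines[i], call. = FALSE)
    }
    tibble::tibble(parent_id = f[1], position = as.integer(f[2]),
                   fraction = as.numeric(f[5]))
  })
  polya <- rows |>
    dplyr::group_by(.data$parent_id) |>
    dplyr::arrange(dplyr::desc(.data$fraction), .data$position, .by_group = TRUE) |>
    dplyr::summarise(main_site = dplyr::first(.data$position),
                     fraction_at_main = dplyr::first(.data$fraction),
                     .groups = "drop")
  list(sites = rows, polya = polya)
}

#' @rdname read_polya_bed
#' @param sites Tibble `parent_id, position, fraction`.
#' @export
write_polya_bed <- function(sites, path) {
  lines <- sprintf("%s\t%d\t%d\tpolyA\t%s", sites$parent_id, sites$position,
                   sites$position + 1L, format(sites$fraction, trim = TRUE))
  writeLines(lines, path)
  invisible(path)
}

#' Serialize / restore the element classifier as JSON
#' @param model An `ee_classifier` from [train_cv()].
#' @param path JSON file path.
#' @export
write_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("weights", "center", "scale")) {
    raw[[f]] <- setNames(as.numeric(raw[[f]]), raw$feature_names)
  }
  structure(raw, class = "ee_classifier")
}

#' Ingest an external library table
#'
#' Normalizes a supplementary library table (already converted to TSV) into
#' the package's manifest layout via an explicit column map. Rows that fail
#' validation (bad alphabet, nonpositive expression) are collected in a
#' rejects tibble, never silently dropped.
#'
#' @param path TSV file path.
#' @param column_map Named character vector mapping manifest fields
#'   (`variant_id`, `variable_region`, and optionally `parent_id`,
#'   `category`, `barcode`, `expression`) to the file's column names.
#' @param category_map Optional named character vector harmonizing the
#'   file's category labels to the package's.
#' @return List `table` (manifest-shaped tibble with optional `mean_au`)
#'   and `rejects` (offending rows with a `reason` column).
#' @export
ingest_supplementary_table <- function(path, column_map,
                                       category_map = NULL) {
  required <- c("variant_id", "variable_region")
  if (!all(required %in% names(column_map))) {
    stop("column_map must name: ",
         paste(setdiff(required, names(column_map)), collapse = ", "),
         call. = FALSE)
  }
  raw <- readr::read_tsv(path, show_col_types = FALSE)
  missing_cols <- setdiff(unname(column_map), names(raw))
  if (length(missing_cols) > 0) {
    stop("input lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  get <- function(field, default = NA_character_) {
    if (field %in% names(column_map)) raw[[column_map[[field]]]]
    else rep(default, nrow(raw))
  }
  tab <- tibble::tibble(
    variant_id = as.character(get("variant_id")),
    parent_id = as.character(get("parent_id")),
    category = as.character(get("category")),
    barcode = as.character(get("barcode")),
    variable_region = toupper(as.character(get("variable_region"))),
    mean_au = suppressWarnings(as.numeric(get("expression", NA)))
  )
  if (!is.null(category_map)) {
    mapped <- unname(category_map[tab$category])
    tab$category <- ifelse(is.na(mapped), tab$category, mapped)
  }
  reason <- rep(NA_character_, nrow(tab))
  bad_seq <- is.na(tab$variable_region) | grepl("[^ACGT]", tab$variable_region)
  reason[bad_seq] <- "non-ACGT variable region"
  dup <- duplicated(tab$variant_id)
  reason[dup & is.na(reason)] <- "duplicate variant_id"
  has_expr <- "expression" %in% names(column_map)
  if (has_expr) {
    bad_expr <- !is.na(tab$mean_au) & tab$mean_au <= 0
    reason[bad_expr & is.na(reason)] <- "nonpositive expression"
  }
  rejects <- dplyr::mutate(tab[!is.na(reason), ], reason = reason[!is.na(reason)])
  list(table = tab[is.na(reason), ], rejects = rejects)
}

#' @rdname ingest_supplementary_table
#' @param table The normalized table to write.
#' @export
write_library_table <- function(table, path) {
  readr::write_tsv(table, path)
  invisible(path)
}

#' Run the full synthetic pipeline
#'
#' design -> simulate -> infer -> profile -> train -> score, on synthetic
#' data with known ground truth, returning a machine-readable report of all
#' summary statistics. Deterministic given `(config, seed)`.
#'
#' @param config A [library_config()]; needs `n_rsd_groups > 0` for the
#'   noise summary and enough parents for grouped CV.
#' @param seed Integer seed for the entire run.
#' @param report_path Optional path to write the report as JSON.
#' @return List `report` (named statistics), `library`, `estimates`,
#'   `profiles`, `element_calls`, `model`, `heldout`, `peak`.
#' @export
run_pipeline <- function(config = library_config(n_native = 50L,
                                                 n_rsd_groups = 10L),
                         seed = 1L, report_path = NULL) {
  lib <- generate_library(config, seed = seed)
  if (nrow(lib$manifest) == 0) stop("stage design: empty library", call. = FALSE)
  norm <- normalize_counts(lib$counts)
  estimates <- fit_library(norm)
  if (!any(estimates$status == "ml_fit")) {
    stop("stage infer: no variant reached an ML fit", call. = FALSE)
  }
  profiles <- fold_change_profiles(lib$manifest, estimates)
  if (nrow(profiles) == 0) stop("stage profile: no profiles", call. = FALSE)
  calls <- call_elements_all(profiles)
  recov <- dplyr::inner_join(calls, lib$elements, by = "parent_id")
  recovered <- with(recov, pmin(element_end.x, element_end.y) >
                            pmax(element_start.x, element_start.y))
  noise <- if (config$n_rsd_groups > 0) {
    grp <- lib$manifest[!is.na(lib$manifest$group_id),
                        c("variant_id", "group_id")]
    median_technical_rsd(estimates, grp,
                         min_size = min(10, config$rsd_group_size))
  } else NULL
  set.seed(seed + 1L)
  instances <- build_instances(profiles, lib$manifest)
  trained <- train_cv(instances)
  cls <- max_effect_classification_rate(trained$heldout)
  fracs <- effect_fractions(profiles)
  repc <- replicate_consistency(profiles)
  pstats <- polyA_relative_stats(profiles, lib$polya)
  wt_ids <- lib$manifest$category == "native_wt" & is.na(lib$manifest$group_id)
  wt_seqs <- setNames(lib$manifest$variable_region[wt_ids],
                      lib$manifest$parent_id[wt_ids])
  score_profiles <- lapply(wt_seqs, function(s) score_native(trained$model, s))
  wt_est <- dplyr::inner_join(
    lib$manifest[wt_ids, c("variant_id", "parent_id")],
    estimates, by = "variant_id")
  peak <- peak_and_correlation(score_profiles, lib$polya, wt_est)
  report <- list(
    seed = seed,
    n_variants = nrow(lib$manifest),
    n_parents = config$n_native,
    median_rsd = if (is.null(noise)) NA_real_ else noise$median_rsd,
    fraction_decrease_2fold = fracs$fraction_decrease,
    fraction_increase_2fold = fracs$fraction_increase,
    replicate_r_squared = repc$r_squared,
    replicate_n_pairs = repc$n_pairs,
    element_recovery_rate = sum(recovered) / config$n_native,
    n_elements_called = nrow(calls),
    single_element_fraction = mean(calls$is_single_element),
    upstream_downstream_t = pstats$t_stat,
    upstream_downstream_p = pstats$p_value,
    modal_max_effect_distance = pstats$modal_distance,
    classification_rate = cls$rate,
    peak_offset = peak$peak_offset,
    ee_expression_r = peak$r
  )
  if (!is.null(report_path)) {
    jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA)
  }
  list(report = report, library = lib, estimates = estimates,
       profiles = profiles, element_calls = calls, model = trained$model,
       heldout = trained$heldout, peak = peak)
}
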