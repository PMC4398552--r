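#' Library design: scanning, saturation and context mutagenesis
#'
#' The design functions produce a *manifest*: a tibble with one row per
#' designed variant and columns
#' `variant_id, parent_id, category, window_start, window_end,
#' replicate_index, barcode, variable_region`.
#' Coordinates are 0-based half-open, position 0 being the first base
#' downstream of the stop codon. The default variable region is 102 bp,
#' flanked (outside this package's scope) by the cloning adapters of the
#' synthesis platform.
#'
#' @name seqdesign
NULL

VARIANT_CATEGORIES <- c(
  "native_wt", "scan10", "scan9", "element_single", "element_double",
  "at_content", "synthetic_terminator"
)

new_variant_row <- function(variant_id, parent_id, category,
                            window_start = NA_integer_, window_end = NA_integer_,
                            replicate_index = 1L, barcode = NA_character_,
                            variable_region) {
  stopifnot(category %in% VARIANT_CATEGORIES)
  tibble::tibble(
    variant_id = variant_id, parent_id = parent_id, category = category,
    window_start = as.integer(window_start), window_end = as.integer(window_end),
    replicate_index = as.integer(replicate_index), barcode = barcode,
    variable_region = variable_region
  )
}

#' Randomly mutate a window of a sequence
#'
#' Every base inside `[start, start + length)` is replaced, uniformly at
#' random, by one of the other three bases, so the Hamming distance between
#' input and output equals `length`. Bases outside the window are untouched.
#'
#' @param seq A nucleotide string over A/C/G/T.
#' @param start 0-based start of the mutation window.
#' @param length Window length in bases.
#' @return The mutated sequence.
#' @export
mutate_window <- function(seq, start, length) {
  assert_dna(seq)
  n <- nchar(seq)
  if (start < 0 || length < 0 || start + length > n) {
    stop("mutation window [", start, ", ", start + length, ") out of bounds for length-",
         n, " sequence", call. = FALSE)
  }
  if (length == 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  idx <- (start + 1L):(start + length)
  # row b of ALT holds the three alternatives to base b
  alt <- matrix(c("C","G","T", "A","G","T", "A","C","T", "A","C","G"),
                nrow = 4, byrow = TRUE, dimnames = list(DNA_BASES, NULL))
  pick <- sample.int(3L, length, replace = TRUE)
  ch[idx] <- alt[cbind(match(ch[idx], DNA_BASES), pick)]
  paste(ch, collapse = "")
}

#' Scanning mutagenesis, 10 bp windows in 10 bp steps
#'
#' Tiles the parent variable region with non-overlapping 10 bp windows
#' starting at position 0 and generates two independent random mutants per
#' window (`replicate_index` 1 and 2). A 102 bp region yields 10 windows;
#' the trailing 2 bp are never mutated.
#'
#' @param parent One manifest row (tibble) of category `native_wt`.
#' @return Manifest tibble of `scan10` variants (20 rows for 102 bp), or an
#'   empty manifest with a warning if the parent is shorter than one window.
#' @export
scan_library_10bp <- function(parent) {
  scan_library(parent, window = 10L, step = 10L, n_replicates = 2L,
               category = "scan10")
}

#' Scanning mutagenesis, 9 bp windows in 3 bp steps
#'
#' Windows start at 0, 3, 6, ... while `start + 9 <= L`; one random mutant
#' per window. On a 102 bp region this gives 32 variants and every position
#' in `[9, 93)` is covered by exactly three windows.
#'
#' @inheritParams scan_library_10bp
#' @return Manifest tibble of `scan9` variants.
#' @export
scan_library_9bp <- function(parent) {
  scan_library(parent, window = 9L, step = 3L, n_replicates = 1L,
               category = "scan9")
}

scan_library <- function(parent, window, step, n_replicates, category) {
  stopifnot(nrow(parent) == 1, parent$category == "native_wt")
  L <- nchar(parent$variable_region)
  if (L < window) {
    warning("parent ", parent$parent_id, " shorter than one ", window,
            " bp window; no variants designed")
    return(new_variant_row(character(0), character(0), character(0),
                           variable_region = character(0))[0, ])
  }
  starts <- seq(0L, L - window, by = step)
  rows <- purrr::map_dfr(starts, function(s) {
    purrr::map_dfr(seq_len(n_replicates), function(r) {
      new_variant_row(
        variant_id = sprintf("%s_%s_w%03d_r%d", parent$parent_id, category, s, r),
        parent_id = parent$parent_id, category = category,
        window_start = s, window_end = s + window, replicate_index = r,
        variable_region = mutate_window(parent$variable_region, s, window)
      )
    })
  })
  rows
}

#' Saturation mutagenesis of an interval
#'
#' Enumerates all single (and optionally all double) base-pair substitutions
#' within `[start, end)`: 3 variants per position, and 9 per unordered
#' position pair when `include_doubles` is set.
#'
#' @param seq The parent nucleotide string.
#' @param start,end Half-open 0-based interval to saturate.
#' @param include_doubles Also enumerate all double mutants (default FALSE).
#' @param parent_id Parent identifier recorded in the manifest.
#' @return Manifest tibble of `element_single` / `element_double` variants.
#' @export
saturation_mutations <- function(seq, start, end, include_doubles = FALSE,
                                 parent_id = "parent") {
  assert_dna(seq)
  stopifnot(start >= 0, end <= nchar(seq), start <= end)
  if (start == end) {
    return(new_variant_row(character(0), character(0), character(0),
                           variable_region = character(0))[0, ])
  }
  ch <- strsplit(seq, "")[[1]]
  positions <- start:(end - 1L)
  singles <- purrr::map_dfr(positions, function(p) {
    alts <- setdiff(DNA_BASES, ch[p + 1L])
    purrr::map_dfr(seq_along(alts), function(i) {
      mut <- ch; mut[p + 1L] <- alts[i]
      new_variant_row(
        variant_id = sprintf("%s_sat1_p%03d_%s", parent_id, p, alts[i]),
        parent_id = parent_id, category = "element_single",
        window_start = p, window_end = p + 1L,
        variable_region = paste(mut, collapse = "")
      )
    })
  })
  if (!include_doubles) return(singles)
  pairs <- utils::combn(positions, 2L)
  doubles <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    p1 <- pairs[1, j]; p2 <- pairs[2, j]
    a1 <- setdiff(DNA_BASES, ch[p1 + 1L]); a2 <- setdiff(DNA_BASES, ch[p2 + 1L])
    purrr::map_dfr(a1, function(b1) purrr::map_dfr(a2, function(b2) {
      mut <- ch; mut[p1 + 1L] <- b1; mut[p2 + 1L] <- b2
      new_variant_row(
        variant_id = sprintf("%s_sat2_p%03d%s_p%03d%s", parent_id, p1, b1, p2, b2),
        parent_id = parent_id, category = "element_double",
        window_start = p1, window_end = p2 + 1L,
        variable_region = paste(mut, collapse = "")
      )
    }))
  })
  dplyr::bind_rows(singles, doubles)
}

#' A/T-content series for a sequence region
#'
#' For each target A/T percentage, flips randomly chosen positions inside
#' `[start, end)` between the A/T and G/C classes (the specific base within
#' the class drawn uniformly) until the region's A/T content is as close to
#' the target as the region length allows. The realized percentage is
#' recorded in `realized_at_pct`.
#'
#' @param seq The parent nucleotide string.
#' @param start,end Half-open 0-based region whose composition is adjusted.
#' @param targets Numeric vector of target A/T percentages in `[0, 100]`.
#' @param parent_id Parent identifier recorded in the manifest.
#' @return Manifest tibble of `at_content` variants with an extra
#'   `realized_at_pct` column.
#' @export
at_content_variants <- function(seq, start, end, targets, parent_id = "parent") {
  assert_dna(seq)
  stopifnot(start >= 0, end <= nchar(seq), end > start,
            all(targets >= 0), all(targets <= 100))
  len <- end - start
  ch <- strsplit(seq, "")[[1]]
  region_idx <- (start + 1L):end
  purrr::map_dfr(seq_along(targets), function(i) {
    target <- targets[i]
    is_at <- ch[region_idx] %in% c("A", "T")
    desired <- round(target / 100 * len)
    delta <- desired - sum(is_at)
    mut <- ch
    if (delta > 0) {
      pool <- region_idx[!is_at]
      flip <- sample(pool, min(delta, length(pool)))
      mut[flip] <- sample(c("A", "T"), length(flip), replace = TRUE)
    } else if (delta < 0) {
      pool <- region_idx[is_at]
      flip <- sample(pool, min(-delta, length(pool)))
      mut[flip] <- sample(c("G", "C"), length(flip), replace = TRUE)
    }
    realized <- 100 * mean(mut[region_idx] %in% c("A", "T"))
    out <- new_variant_row(
      variant_id = sprintf("%s_at%03d_t%02d", parent_id, round(target), i),
      parent_id = parent_id, category = "at_content",
      window_start = start, window_end = end,
      variable_region = paste(mut, collapse = "")
    )
    out$realized_at_pct <- realized
    out$target_at_pct <- target
    out
  })
}

#' Compose a synthetic terminator inside a non-terminating context
#'
#' Embeds efficiency-element (EE), positioning-element (PE) and
#' cleavage-site sequences at fixed offsets into a context sequence by
#' replacement, preserving the context length. Placements must be
#' non-overlapping and ordered EE < PE < cleavage along the sequence, the
#' canonical yeast polyadenylation-signal arrangement.
#'
#' @param context Nucleotide string, typically a mutated non-terminating
#'   3' end region.
#' @param layout Tibble with columns `element_name` (one of
#'   `"EE"`, `"PE"`, `"cleavage"`), `sequence`, `offset` (0-based).
#' @return The composed sequence (same length as `context`).
#' @export
compose_terminator <- function(context, layout) {
  assert_dna(context)
  stopifnot(all(c("element_name", "sequence", "offset") %in% names(layout)))
  if (nrow(layout) == 0) return(context)
  layout <- layout[order(layout$offset), ]
  ends <- layout$offset + nchar(layout$sequence)
  if (any(layout$offset < 0) || any(ends > nchar(context))) {
    stop("element placement outside context", call. = FALSE)
  }
  if (nrow(layout) > 1 && any(layout$offset[-1] < ends[-nrow(layout)])) {
    stop("element placements overlap", call. = FALSE)
  }
  canon <- c(EE = 1L, PE = 2L, cleavage = 3L)
  ord <- canon[layout$element_name]
  if (any(is.na(ord)) || is.unsorted(ord, strictly = TRUE)) {
    stop("placements must be ordered EE < PE < cleavage", call. = FALSE)
  }
  out <- context
  for (i in seq_len(nrow(layout))) {
    out <- replace_at0(out, layout$offset[i], layout$sequence[i])
  }
  out
}

#' Extract element sequences back out of a composed terminator
#' @param seq A composed terminator sequence.
#' @param layout The layout used to compose it.
#' @return Character vector of the subsequences at each placement.
#' @export
extract_terminator <- function(seq, layout) {
  vapply(seq_len(nrow(layout)), function(i) {
    subseq0(seq, layout$offset[i], layout$offset[i] + nchar(layout$sequence[i]))
  }, character(1))
}

#' Assign unique 11 bp barcodes to a manifest
#'
#' Barcodes are random 11-mers carrying a base-4 checksum in their last
#' position, which guarantees a pairwise Hamming distance of at least 2
#' between any two assigned barcodes. Barcodes with homopolymer runs longer
#' than 4 are rejected. Assignment is deterministic under a fixed RNG seed.
#'
#' @param variants Manifest tibble; the `barcode` column is (re)filled.
#' @param barcode_length Barcode length (default 11).
#' @return The manifest with barcodes assigned.
#' @export
assign_barcodes <- function(variants, barcode_length = 11L) {
  n <- nrow(variants)
  if (n == 0) return(variants)
  if (n > 4^(barcode_length - 2)) {
    stop("requested ", n, " barcodes exceeds the feasible checksum code size",
         call. = FALSE)
  }
  seen <- new.env(hash = TRUE)
  out <- character(n)
  filled <- 0L
  while (filled < n) {
    need <- n - filled
    batch <- ceiling(need * 1.3) + 16L
    prefix <- matrix(sample.int(4L, batch * (barcode_length - 1L), replace = TRUE) - 1L,
                     nrow = batch)
    check <- (-rowSums(prefix)) %% 4L
    codes <- cbind(prefix, check)
    bc <- apply(codes + 1L, 1L, function(r) paste(DNA_BASES[r], collapse = ""))
    ok <- !grepl("A{5,}|C{5,}|G{5,}|T{5,}", bc)
    for (b in bc[ok]) {
      if (filled == n) break
      if (is.null(seen[[b]])) {
        seen[[b]] <- TRUE
        filled <- filled + 1L
        out[filled] <- b
      }
    }
  }
  variants$barcode <- out
  variants
}

#' Screen designed sequences for cloning restriction sites
#'
#' The library cloning scheme uses SexAI (`ACCWGGT`) and AvrII (`CCTAGG`)
#' sites in the fixed adapters; internal occurrences in a designed variable
#' region would be cut during cloning. Occurrences are reported as warnings,
#' not rejected.
#'
#' @param variants Manifest tibble.
#' @return Logical vector, `TRUE` where a restriction site was found
#'   (invisibly); warnings name the offending variants.
#' @export
screen_restriction_sites <- function(variants) {
  hit <- grepl("ACC[AT]GGT|CCTAGG", variants$variable_region)
  if (any(hit)) {
    warning(sum(hit), " designed region(s) contain SexAI/AvrII sites: ",
            paste(utils::head(variants$variant_id[hit], 5), collapse = ", "),
            if (sum(hit) > 5) ", ..." else "")
  }
  invisible(hit)
}
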