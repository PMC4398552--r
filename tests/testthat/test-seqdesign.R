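test_that("mutate_window changes exactly the window, uniformly over alternatives", {
  expect_identical(mutate_window("ACGTACGTAC", 0, 0), "ACGTACGTAC")

  set.seed(1)
  out <- mutate_window("ACGTACGTAC", 2, 3)
  diff_pos <- which(strsplit(out, "")[[1]] != strsplit("ACGTACGTAC", "")[[1]])
  expect_identical(diff_pos, 3:5)  # 1-based positions of 0-based window [2,5)

  # Monte-Carlo: on "AAAA" fully mutated, A never appears and each of C/G/T
  # has frequency 1/3 +- 0.02 per position
  set.seed(2)
  draws <- replicate(10000, strsplit(mutate_window("AAAA", 0, 4), "")[[1]])
  expect_false(any(draws == "A"))
  for (b in c("C", "G", "T")) {
    freq <- rowMeans(draws == b)
    expect_true(all(abs(freq - 1 / 3) < 0.02))
  }

  expect_error(mutate_window("ACGT", 2, 5), "out of bounds")
})

test_that("scan10 tiles a 102 bp region with 10 windows x 2 replicates", {
  set.seed(3)
  parent <- make_parent()
  lib <- scan_library_10bp(parent)
  expect_equal(nrow(lib), 20)
  expect_equal(sort(unique(lib$window_start)), seq(0L, 90L, by = 10L))
  expect_true(all(lib$window_end - lib$window_start == 10))
  # union of windows covers [0,100); trailing 2 bp untouched
  expect_equal(max(lib$window_end), 100L)
  # every variant differs from the parent at exactly its window positions
  pch <- strsplit(parent$variable_region, "")[[1]]
  for (i in seq_len(nrow(lib))) {
    vch <- strsplit(lib$variable_region[i], "")[[1]]
    d <- which(vch != pch) - 1L  # 0-based
    expect_equal(length(d), 10)
    expect_true(all(d >= lib$window_start[i] & d < lib$window_end[i]))
  }
})

test_that("scan9 windows step by 3 and cover interior positions three times", {
  set.seed(4)
  parent <- make_parent()
  lib <- scan_library_9bp(parent)
  expect_equal(nrow(lib), 32)
  expect_equal(lib$window_start, seq(0L, 93L, by = 3L))
  # coverage count per position by enumeration
  cover <- integer(102)
  for (i in seq_len(nrow(lib))) {
    idx <- (lib$window_start[i] + 1L):lib$window_end[i]
    cover[idx] <- cover[idx] + 1L
  }
  expect_true(all(cover[10:93] == 3))  # 0-based [9, 93)
  for (i in seq_len(nrow(lib))) {
    expect_equal(hamming(lib$variable_region[i], parent$variable_region), 9)
  }
})

test_that("scanning a too-short parent warns and returns no variants", {
  parent <- make_parent(seq = "ACGTA", len = 5L)
  expect_warning(lib <- scan_library_10bp(parent), "shorter")
  expect_equal(nrow(lib), 0)
})

test_that("saturation mutagenesis enumerates singles and doubles without duplicates", {
  set.seed(5)
  seq <- random_dna(20)
  singles <- saturation_mutations(seq, 5, 11)
  expect_equal(nrow(singles), 18)  # 3 per position x 6
  expect_true(all(vapply(singles$variable_region, hamming, numeric(1), b = seq) == 1))

  both <- saturation_mutations(seq, 5, 11, include_doubles = TRUE)
  expect_equal(nrow(both), 18 + choose(6, 2) * 9)  # 153
  expect_equal(anyDuplicated(both$variable_region), 0)
  expect_false(any(both$variable_region == seq))

  expect_equal(nrow(saturation_mutations(seq, 5, 5)), 0)
})

test_that("A/T-content series hits targets and is monotone in the target", {
  set.seed(6)
  # region of 20 bp with exactly 10 A/T bases
  seq <- paste0(strrep("AG", 10), strrep("C", 10))  # [0,20) has 10 A
  v80 <- at_content_variants(seq, 0, 20, targets = 80)
  expect_equal(v80$realized_at_pct, 80)
  expect_equal(hamming(v80$variable_region, seq), 6)  # 0.8*20 - 10 = 6 flips
  # untouched outside the region
  expect_identical(substr(v80$variable_region, 21, 30), strrep("C", 10))

  same <- at_content_variants(seq, 0, 20, targets = 50)
  expect_identical(same$variable_region, seq)

  series <- at_content_variants(seq, 0, 20, targets = c(0, 25, 50, 75, 100))
  expect_false(is.unsorted(series$realized_at_pct))
})

test_that("terminator composition embeds elements and round-trips", {
  set.seed(7)
  context <- random_dna(102)
  layout <- tibble::tibble(
    element_name = c("EE", "PE", "cleavage"),
    sequence = c("TATATA", "AAGAAA", "TTTGTT"),
    offset = c(20L, 40L, 60L))
  out <- compose_terminator(context, layout)
  expect_equal(nchar(out), 102)
  expect_identical(extract_terminator(out, layout), layout$sequence)
  expect_identical(compose_terminator(context, layout[0, ]), context)

  bad_order <- layout[c(2, 1, 3), ]
  bad_order$offset <- c(20L, 40L, 60L)  # PE before EE
  expect_error(compose_terminator(context, bad_order), "ordered")
  overlap <- layout
  overlap$offset <- c(20L, 24L, 60L)
  expect_error(compose_terminator(context, overlap), "overlap")
})

test_that("barcodes are unique 11-mers at pairwise Hamming distance >= 2", {
  set.seed(8)
  manifest <- purrr::map_dfr(1:500, function(i) make_parent(parent_id = paste0("p", i)))
  bc <- assign_barcodes(manifest)$barcode
  expect_equal(length(unique(bc)), 500)
  expect_true(all(nchar(bc) == 11))
  expect_false(any(grepl("A{5,}|C{5,}|G{5,}|T{5,}", bc)))
  # pairwise Hamming on a sample of pairs
  idx <- utils::combn(sample.int(500, 40), 2)
  dmin <- min(apply(idx, 2, function(p) hamming(bc[p[1]], bc[p[2]])))
  expect_gte(dmin, 2)
  # seeded determinism
  set.seed(8)
  manifest2 <- purrr::map_dfr(1:500, function(i) make_parent(parent_id = paste0("p", i)))
  expect_identical(assign_barcodes(manifest2)$barcode, bc)
})

test_that("restriction-site screening flags SexAI/AvrII occurrences", {
  m <- make_parent(seq = paste0(random_dna(40), "CCTAGG", random_dna(56)))
  expect_warning(hit <- screen_restriction_sites(m), "SexAI/AvrII")
  expect_true(hit)
  set.seed(9)
  clean <- make_parent(seq = strrep("AC", 51))
  expect_silent(expect_false(screen_restriction_sites(clean)))
})
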