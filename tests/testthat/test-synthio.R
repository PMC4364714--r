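test_that("reference generation honours length, alphabet, GC and seed", {
  ref <- make_reference(100, gc_fraction = 0.5, seed = 7)
  expect_equal(nchar(ref$sequence), 100)
  expect_false(grepl("[^ACGT]", ref$sequence))

  at_only <- make_reference(1000, gc_fraction = 0, seed = 1)
  expect_false(grepl("[GC]", at_only$sequence))

  expect_identical(
    make_reference(5000, 0.42, seed = 3)$sequence,
    make_reference(5000, 0.42, seed = 3)$sequence
  )

  big <- make_reference(1e5, gc_fraction = 0.42, seed = 2)
  gc <- sum(strsplit(big$sequence, "")[[1]] %in% c("G", "C")) / 1e5
  expect_lt(abs(gc - 0.42), 0.02)

  expect_error(make_reference(0), "positive")
})

test_that("insertion allele length arithmetic and truth record match construction", {
  # Fig-scale arithmetic: 2 Mb host + 26 kb duplication + 700 kb array
  ref <- make_reference(10000, seed = 1)
  units <- make_transgene_units(c(a = 1000, b = 1000), seed = 2)
  al <- build_insertion_allele(ref, site = 4001, units, copies = c(2, 1),
                               dup_length = 500)
  expect_equal(nchar(al$sequence), 10000 + 500 + 3000)
  expect_equal(al$truth$array_length, 3000)
  expect_equal(al$truth$unit_copies, c(a = 2L, b = 1L))
  expect_equal(unname(al$truth$dup_interval), c(4001, 4500))
  # duplicated bases appear before and after the array
  dup_seq <- substr(ref$sequence, 4001, 4500)
  expect_equal(substr(al$sequence, 4001, 4500), dup_seq)
  expect_equal(substr(al$sequence, 4001 + 500 + 3000, 4500 + 500 + 3000),
               dup_seq)
  # interleaved array: a, b, a
  expect_equal(substr(al$sequence, 4501, 5500), units$sequence[1])
  expect_equal(substr(al$sequence, 5501, 6500), units$sequence[2])
  expect_equal(substr(al$sequence, 6501, 7500), units$sequence[1])

  # zero-length duplication: mutant = ref + array
  al0 <- build_insertion_allele(ref, site = 4001, units, copies = c(1, 0),
                                dup_length = 0)
  expect_equal(nchar(al0$sequence), 10000 + 1000)

  expect_error(
    build_insertion_allele(ref, site = 4001, units, copies = c(0, 0)),
    "copy"
  )
  expect_error(
    build_insertion_allele(ref, site = 9999, units, copies = c(1, 1),
                           dup_length = 500),
    "out of range"
  )
})

test_that("read simulator emits the coverage-implied number of pairs", {
  # haploid 100 kb at 30x, 100 bp reads -> 7,500 pairs within 1%
  ref <- make_reference(1e5, seed = 4)
  sim <- simulate_paired_reads(ref, coverage = 30, seed = 5)
  expect_lt(abs(sim$params$n_pairs - 7500) / 7500, 0.01)
  expect_equal(nrow(sim$alignments), 2 * sim$params$n_pairs)
  expect_error(simulate_paired_reads(ref, coverage = 0), "positive")
  expect_error(simulate_paired_reads(ref, coverage = 5, insert_mean = 150),
               "insert_mean")
})

test_that("error-free reads are exact substrings of their source allele", {
  al <- small_insertion(seed = 2)
  sim <- simulate_paired_reads(al, coverage = 0.3, seed = 3,
                               emit_sequences = TRUE)
  fr <- sim$fragments
  rl <- sim$params$read_len
  seqs <- sim$reads %>% dplyr::left_join(fr, by = "read_id")
  fwd <- seqs %>% dplyr::filter(mate == 1)
  expect_true(all(
    substring(al$sequence, fwd$start, fwd$start + rl - 1) == fwd$seq
  ))
  # reverse mates are reverse complements of the fragment end
  rev <- seqs %>% dplyr::filter(mate == 2) %>% head(50)
  rc <- function(s) chartr(
    "ACGT", "TGCA",
    vapply(strsplit(s, ""), function(x) paste(rev(x), collapse = ""), "")
  )
  expect_true(all(
    rc(substring(al$sequence, rev$start + rev$frag_len - rl,
                 rev$start + rev$frag_len - 1)) == rev$seq
  ))
})

test_that("read simulation is reproducible and respects fragment bounds", {
  al <- small_insertion(seed = 2)
  s1 <- simulate_paired_reads(al, coverage = 1, seed = 9)
  s2 <- simulate_paired_reads(al, coverage = 1, seed = 9)
  expect_identical(s1$alignments, s2$alignments)
  expect_true(all(s1$fragments$frag_len >= 200 & s1$fragments$frag_len <= 800))
})

test_that("chimeric pairs in the alignment stream equal the fragment-gap oracle", {
  for (seed in 1:3) {
    al <- small_insertion(seed = seed)
    sim <- simulate_paired_reads(al, coverage = 20, seed = seed + 50)
    found <- collect_chimeric_pairs(sim, "chr10", c("u1", "u2"))
    expect_equal(nrow(found), oracle_chimeric_count(sim, al))
  }
})

test_that("junction-spanning truth fragments round-trip as non-proper pairs", {
  al <- small_insertion(seed = 6)
  sim <- simulate_paired_reads(al, coverage = 10, seed = 7)
  b <- junction_boundaries(al)
  rl <- sim$params$read_len
  overlapping <- sim$fragments %>%
    dplyr::filter(
      allele %in% 1:2,
      (start <= b["left"] & start + frag_len - 1 > b["left"]) |
        (start <= b["right"] & start + frag_len - 1 > b["right"])
    )
  aln <- sim$alignments %>% dplyr::filter(read_id %in% overlapping$read_id)
  # every host/array junction-overlapping fragment yields a non-proper pair
  expect_true(all(!aln$proper))
  # and every mapped host/transgene chimeric pair overlaps a junction
  chim <- collect_chimeric_pairs(sim, "chr10", c("u1", "u2"))
  expect_true(all(chim$read_id %in% overlapping$read_id))
})

test_that("cohort fractions follow the truncated-Gaussian threshold model", {
  co <- simulate_cohort(200, 200, mu_female = 95, sigma = 0.001,
                        threshold = 80, seed = 1)
  expect_equal(sum(co$megacolon[co$sex == "F"]), 0)

  big <- simulate_cohort(20000, 0, mu_male = 79, sigma = 5, threshold = 80,
                         seed = 2)
  pen <- mean(big$megacolon)
  expect_lt(abs(pen - pnorm((80 - 79) / 5)), 0.01) # Phi closed form 0.5793

  fem_only <- simulate_cohort(0, 10, seed = 3)
  expect_true(all(fem_only$sex == "F"))
  expect_error(simulate_cohort(-1, 5), "non-negative")

  # neonate defaults differ from weaning defaults
  neo <- simulate_cohort(2000, 2000, age_group = "neonate", seed = 4)
  m <- mean_ganglionic_by_sex(neo)
  expect_lt(abs(m$mean[m$sex == "M"] - 74), 0.5)
  expect_lt(abs(m$mean[m$sex == "F"] - 90), 0.5)
})

test_that("track generator obeys degenerate limits and recovers its speed", {
  still <- simulate_tracks(3, duration = 30, dt = 5, speed_mu = 0, speed_sd = 0,
                           seed = 1)
  expect_true(all(still$x == 0 & still$y == 0))

  straight <- simulate_tracks(5, duration = 50, dt = 5, kappa = 1e7,
                              reference_angle = pi / 4, seed = 2)
  dirs <- track_metrics(straight, reference_angle = pi / 4)
  expect_true(all(abs(dirs$mean_deviation) < 1e-3))
  expect_true(all(dirs$R > 0.999))

  tr <- simulate_tracks(200, duration = 180, dt = 5, speed_mu = 0.58,
                        speed_sd = 0.1, seed = 3)
  sp <- track_metrics(tr)$mean_speed
  expect_lt(abs(mean(sp) - 0.58) / 0.58, 0.05)

  expect_error(simulate_tracks(2, kappa = -1), "kappa")
})

test_that("count generator matches the NB mean-variance law and Poisson limit", {
  pois <- simulate_counts(2000, dispersion = 0, mean_log_mu = log(50),
                          sd_log_mu = 0, seed = 1)
  # per-gene variance ~ mean across genes with common mu
  expect_lt(abs(var(as.vector(pois$counts)) / mean(pois$counts) - 1), 0.05)

  nb <- simulate_counts(3000, dispersion = 0.2, mean_log_mu = log(100),
                        sd_log_mu = 0, seed = 2)
  v <- var(as.vector(nb$counts))
  mu <- mean(nb$counts)
  expect_lt(abs(v / (mu + 0.2 * mu^2) - 1), 0.1)

  expect_error(simulate_counts(10, dispersion = -1), "dispersion")
  expect_error(
    simulate_counts(10, de_spec = c(gene00001 = -2), seed = 1),
    "positive ratios"
  )
})

test_that("FASTA and FASTQ writers emit well-formed records", {
  al <- small_insertion(seed = 8)
  sim <- simulate_paired_reads(al, coverage = 0.05, seed = 9,
                               emit_sequences = TRUE)
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_sim_fasta(al, fa)
  back <- Biostrings::readDNAStringSet(fa)
  expect_setequal(names(back), c("chr10", "u1", "u2"))
  expect_equal(as.character(back[["u1"]]), al$units$sequence[1])

  prefix <- withr::local_tempfile()
  paths <- write_sim_fastq(sim, prefix)
  l1 <- readr::read_lines(paths[1])
  expect_equal(length(l1), 4 * sim$params$n_pairs)
  expect_true(all(startsWith(l1[seq(1, length(l1), by = 4)], "@")))
  expect_true(all(nchar(l1[seq(2, length(l1), by = 4)]) == 100))
})
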