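# Shared small-scale simulation fixtures, built in code at test time.

# A compact insertion architecture: 300 kb host, 6 kb target-site
# duplication, 20 kb concatemer of two 1 kb units (10 copies each).
small_insertion <- function(seed = 1, zygosity = "hom",
                            copies = c(10L, 10L), dup_length = 6000) {
  ref <- make_reference(3e5, seed = seed)
  units <- make_transgene_units(c(u1 = 1000, u2 = 1000), seed = seed + 100)
  build_insertion_allele(ref, site = 150001, units, copies = copies,
                         dup_length = dup_length, zygosity = zygosity)
}

small_unit_lengths <- c(u1 = 1000, u2 = 1000)

# Allele coordinates of the two host/array junction boundaries: the last
# base before the array and the last base of the array. Derived directly
# from the construction arithmetic, independently of the segment map.
junction_boundaries <- function(allele) {
  tr <- allele$truth
  before_array <- tr$host_site + tr$dup_length - 1
  c(left = before_array, right = before_array + tr$array_length)
}

# Fragment-level oracle: a pair is host<->transgene chimeric exactly when a
# host/array junction falls in the inner gap of the fragment, so that one
# whole read lies in host sequence and the other whole read in the array.
oracle_chimeric_count <- function(sim, allele) {
  b <- junction_boundaries(allele)
  fr <- sim$fragments
  rl <- sim$params$read_len
  spans <- function(bnd) {
    fr$start + rl - 1 <= bnd & fr$start + fr$frag_len - rl >= bnd + 1
  }
  # mutant allele copies only (the reference copy of a het has no junction)
  n_mutant <- if (allele$truth$zygosity == "hom") 1:2 else 1
  sum((spans(b["left"]) | spans(b["right"])) & fr$allele %in% n_mutant)
}

# hand-built depth profile for detector unit tests
fake_profile <- function(depth_norm, window = 1000, contig = "chr",
                         baseline = 30) {
  n <- length(depth_norm)
  prof <- tibble::tibble(
    contig = contig,
    start = (seq_len(n) - 1) * window + 1,
    end = seq_len(n) * window,
    n_reads = as.integer(round(depth_norm * baseline)),
    depth_norm = depth_norm
  )
  attr(prof, "baseline") <- baseline
  attr(prof, "window") <- window
  attr(prof, "baseline_contig") <- contig
  class(prof) <- c("depth_profile", class(prof))
  prof
}
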