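#' Generate a random reference sequence
#'
#' Draws an i.i.d. DNA sequence over ACGT with a requested GC fraction. Used
#' as a stand-in host chromosome (e.g. a gene-desert region of a mouse
#' autosome) for insertion-mapping simulations.
#'
#' @param length Sequence length in bases (>= 1).
#' @param gc_fraction Target GC fraction in `[0, 1]`. Default 0.42, a typical
#'   mammalian autosomal value.
#' @param seed Integer seed for reproducibility, or `NULL` to use the current
#'   RNG stream.
#' @param name Contig name.
#' @return An object of class `reference_genome`: a list with `name`,
#'   `sequence` (a single character string) and `length`.
#' @examples
#' ref <- make_reference(1000, gc_fraction = 0.5, seed = 1)
#' nchar(ref$sequence)
#' @export
make_reference <- function(length, gc_fraction = 0.42, seed = NULL,
                           name = "chr10") {
  if (!is.numeric(length) || length(length) != 1 || length < 1) {
    abort("`length` must be a single positive number of bases")
  }
  if (gc_fraction < 0 || gc_fraction > 1) {
    abort("`gc_fraction` must lie in [0, 1]")
  }
  local_seed(seed)
  length <- as.integer(length)
  p <- c(
    A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
    G = gc_fraction / 2, T = (1 - gc_fraction) / 2
  )
  bases <- sample(names(p), length, replace = TRUE, prob = p)
  structure(
    list(name = name, sequence = paste(bases, collapse = ""), length = length),
    class = "reference_genome"
  )
}

#' @export
print.reference_genome <- function(x, ...) {
  cat(sprintf(
    "<reference_genome> %s: %s bases\n", x$name, format(x$length, big.mark = ",")
  ))
  invisible(x)
}

#' Construct transgene units
#'
#' Builds the tandem-array building blocks of a transgene concatemer: each
#' unit is one co-injected construct (e.g. a pigmentation-rescue minigene and
#' a fluorescent NCC reporter). Unit sequences are random; only their lengths
#' and names matter to the depth-based copy-number arithmetic.
#'
#' @param lengths Named integer vector of unit lengths in bases (each >= 1000).
#' @param gc_fraction GC fraction for the random unit sequences.
#' @param seed Integer seed or `NULL`.
#' @return A tibble with columns `name`, `sequence`, `length`.
#' @examples
#' make_transgene_units(c("Tyr-minigene" = 7000, "SRYp-YFP" = 7000), seed = 1)
#' @export
make_transgene_units <- function(lengths = c("Tyr-minigene" = 7000,
                                             "SRYp-YFP" = 7000),
                                 gc_fraction = 0.5, seed = NULL) {
  if (is.null(names(lengths)) || anyDuplicated(names(lengths))) {
    abort("`lengths` must be uniquely named")
  }
  if (any(lengths < 1000)) abort("transgene units must be >= 1 kb")
  local_seed(seed)
  tibble(
    name = names(lengths),
    sequence = purrr::map_chr(
      as.integer(lengths),
      function(l) make_reference(l, gc_fraction, seed = NULL)$sequence
    ),
    length = as.integer(lengths)
  )
}

#' Build a transgene insertion allele
#'
#' Inserts a concatemer of transgene units into a host reference, flanked on
#' both sides by a target-site duplication: the `dup_length` host bases
#' starting at `site` appear once before and once after the array. The
#' mutant allele is therefore `ref$length + dup_length + array_length` bases
#' long. The returned object records the full ground truth (duplication
#' interval, junction coordinates, per-unit copies, array length) and a
#' segment map used by the read simulator to assign truth alignments.
#'
#' All coordinates are 1-based and inclusive.
#'
#' @param ref A `reference_genome`.
#' @param site 1-based host position of the first duplicated base.
#' @param units Tibble of transgene units (see [make_transgene_units()]).
#' @param copies Integer vector, copies of each unit per allele (same order
#'   as `units`); at least one must be >= 1. Units are interleaved in the
#'   array (equimolar co-injection).
#' @param dup_length Length of the target-site duplication in bases (>= 0).
#' @param zygosity `"hom"` or `"het"`.
#' @return An object of class `insertion_allele`: list with `sequence`
#'   (mutant allele), `ref`, `units`, `segments` (tibble mapping allele
#'   intervals to contig coordinates) and `truth` (class `insertion_truth`).
#' @examples
#' ref <- make_reference(50000, seed = 1)
#' units <- make_transgene_units(c(u1 = 1000, u2 = 1000), seed = 2)
#' al <- build_insertion_allele(ref, site = 20001, units, copies = c(3, 3),
#'                              dup_length = 2000)
#' al$truth$array_length
#' @export
build_insertion_allele <- function(ref, site, units, copies,
                                   dup_length = 26000, zygosity = "hom") {
  stopifnot(inherits(ref, "reference_genome"))
  assert_df_cols(units, c("name", "sequence", "length"))
  if (length(copies) != nrow(units)) {
    abort("`copies` must have one entry per transgene unit")
  }
  if (all(copies == 0)) abort("at least one unit must have >= 1 copy")
  if (any(copies < 0)) abort("`copies` must be non-negative")
  if (dup_length < 0) abort("`dup_length` must be >= 0")
  if (site < 1 || site + dup_length - 1 > ref$length) {
    abort("duplication interval [site, site + dup_length - 1] out of range")
  }
  copies <- as.integer(copies)

  # interleaved array order: u1 u2 u1 u2 ... until each unit's copies run out
  order_idx <- unlist(purrr::map(seq_len(max(copies)), function(i) {
    which(copies >= i)
  }))
  array_units <- units[order_idx, ]
  array_length <- sum(array_units$length)

  dup_end <- site + dup_length - 1 # 0-length dup -> empty interval
  prefix_end <- if (dup_length > 0) dup_end else site - 1
  arr_start <- prefix_end + 1
  arr_ends <- arr_start - 1 + cumsum(array_units$length)
  arr_starts <- arr_ends - array_units$length + 1

  segments <- bind_rows(
    tibble(
      start = 1, end = prefix_end, contig = ref$name,
      contig_start = 1, class = "host", unit = NA_character_
    ),
    tibble(
      start = arr_starts, end = arr_ends, contig = array_units$name,
      contig_start = 1, class = "transgene", unit = array_units$name
    ),
    tibble(
      start = max(arr_ends) + 1,
      end = max(arr_ends) + 1 + (ref$length - site),
      contig = ref$name, contig_start = site, class = "host",
      unit = NA_character_
    )
  ) %>% filter(.data$end >= .data$start)

  sequence <- paste0(
    substr(ref$sequence, 1, prefix_end),
    paste(array_units$sequence, collapse = ""),
    substr(ref$sequence, site, ref$length)
  )

  truth <- structure(
    list(
      host_site = site,
      dup_length = dup_length,
      dup_interval = c(start = site, end = dup_end),
      # host-coordinate breakpoints bracketing the insertion: the array sits
      # between the two copies of the duplicated segment
      breakpoints = c(left = site, right = if (dup_length > 0) dup_end else site),
      unit_copies = setNames(copies, units$name),
      array_length = array_length,
      zygosity = match.arg(zygosity, c("hom", "het"))
    ),
    class = "insertion_truth"
  )

  structure(
    list(
      sequence = sequence, ref = ref, units = units,
      segments = segments, truth = truth
    ),
    class = "insertion_allele"
  )
}

#' @export
print.insertion_allele <- function(x, ...) {
  tr <- x$truth
  cat(sprintf(
    paste0(
      "<insertion_allele> host %s (%s bases) + %s kb array (%s), ",
      "%s kb target-site duplication at %s\n"
    ),
    x$ref$name, format(x$ref$length, big.mark = ","),
    format(tr$array_length / 1000), tr$zygosity,
    format(tr$dup_length / 1000), format(tr$host_site, big.mark = ",")
  ))
  invisible(x)
}
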