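#' Predict the amplicon length of a template-free primer pair
#'
#' Telomere qPCR primers of the Cawthon design amplify each other rather than
#' a fixed genomic locus: the two primers anneal head-to-head through their 3'
#' ends and polymerase extension of that duplex defines the product. The model
#' implemented here finds the largest `k` such that the 3'-terminal `k` bases
#' of `primer_a` are perfectly Watson-Crick complementary, read antiparallel,
#' to the 3'-terminal `k` bases of `primer_b`; the predicted product length is
#' then `nchar(a) + nchar(b) - k`. Internal mismatches and partial overlaps
#' are not modelled. With no 3' complementarity at all there is no predicted
#' product and an error is raised.
#'
#' @param primer_a,primer_b Primer sequences, 5' to 3', over A/C/G/T.
#' @return Predicted product length in base pairs (integer).
#' @export
#' @examples
#' predict_primer_product_length("AAAA", "TTTT")  # full overlap: 4 bp
#' p <- tel_primers()
#' predict_primer_product_length(p[["telg"]], p[["telc"]])
predict_primer_product_length <- function(primer_a, primer_b) {
  a <- clean_primer(primer_a, "primer_a")
  b <- clean_primer(primer_b, "primer_b")
  k <- max_three_prime_overlap(a, b)
  if (k == 0) {
    stop("no 3'-terminal complementary overlap: no predicted product",
         call. = FALSE)
  }
  nchar(a) + nchar(b) - k
}

clean_primer <- function(x, name) {
  if (length(x) != 1 || is.na(x) || nchar(x) == 0) {
    stop(name, " must be a non-empty sequence", call. = FALSE)
  }
  x <- toupper(x)
  if (grepl("[^ACGT]", x)) {
    stop(name, " contains characters outside A/C/G/T", call. = FALSE)
  }
  x
}

max_three_prime_overlap <- function(a, b) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  kmax <- min(length(av), length(bv))
  best <- 0L
  for (k in seq_len(kmax)) {
    ta <- av[(length(av) - k + 1):length(av)]
    tb <- bv[(length(bv) - k + 1):length(bv)]
    # antiparallel pairing: 3' tail of a against reversed 3' tail of b
    if (all(comp[ta] == rev(tb))) best <- k
  }
  best
}

#' Telomere primer pair (Telg/Telc)
#'
#' The telomere-repeat primer pair used for relative telomere quantification,
#' 5' to 3'. The two primers form a 3-base 3' overlap, giving a predicted
#' 79 bp product.
#'
#' @return Named character vector with elements `telg` and `telc`.
#' @export
tel_primers <- function() {
  c(telg = "ACACTAAGGTTTGGGTTTGGGTTTGGGTTTGGGTTAGTGT",
    telc = "TGTTAGGTATCCCTATCCCTATCCCTATCCCTATCCCTAACA")
}
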