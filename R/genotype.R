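#' Describe a deletion allele assayed by PCR fragment length
#'
#' Small fixture for the genotyping arithmetic: a wildtype amplicon of
#' known length carries an internal deletion in the mutant allele, so the
#' two alleles separate by fragment size on a gel. Defaults describe the
#' studied null allele: an 11-nucleotide deletion in a 152 bp amplicon
#' causing a frameshift after the 10th residue.
#'
#' @param wt_amplicon_len Wildtype amplicon length in base pairs.
#' @param deletion_len Deleted length in nucleotides (less than the
#'   amplicon length).
#' @param frameshift_after_residue Amino-acid position after which the
#'   frame shifts in the mutant protein.
#' @return An `allele_model` list with the fields above plus
#'   `is_frameshift` (`TRUE` when the deletion length is not a multiple of
#'   three).
#' @examples
#' allele_model()$is_frameshift
#' @export
allele_model <- function(wt_amplicon_len = 152L, deletion_len = 11L,
                         frameshift_after_residue = 10L) {
  if (deletion_len < 0 || deletion_len >= wt_amplicon_len) {
    abort_zfecg("`deletion_len` must be >= 0 and smaller than the amplicon.", "zfecg_input")
  }
  structure(
    list(
      wt_amplicon_len = as.integer(wt_amplicon_len),
      deletion_len = as.integer(deletion_len),
      frameshift_after_residue = as.integer(frameshift_after_residue),
      is_frameshift = deletion_len %% 3L != 0L
    ),
    class = "allele_model"
  )
}

#' Expected PCR fragment lengths for a genotype
#'
#' @param genotype One of `"+/+"`, `"+/-"` or `"-/-"`.
#' @param allele An [allele_model()].
#' @return Integer vector of distinct fragment lengths in base pairs,
#'   longest first.
#' @examples
#' genotype_fragments("+/-")
#' @export
genotype_fragments <- function(genotype = c("+/+", "+/-", "-/-"),
                               allele = allele_model()) {
  genotype <- match.arg(genotype)
  wt <- allele$wt_amplicon_len
  mut <- wt - allele$deletion_len
  out <- switch(genotype,
    "+/+" = wt,
    "-/-" = mut,
    "+/-" = c(wt, mut)
  )
  sort(unique(as.integer(out)), decreasing = TRUE)
}
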