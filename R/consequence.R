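# Consequence classification against MANE-transcript annotation terms.

# Sequence-ontology terms mapped to each class. pLoF covers nonsense,
# frameshift and essential splice-site terms; missense covers missense and
# in-frame insertions/deletions. Everything else is non-protein-altering here.
.PLOF_TERMS <- c(
  "stop_gained",
  "frameshift_variant",
  "splice_acceptor_variant",
  "splice_donor_variant"
)

.MISSENSE_TERMS <- c(
  "missense_variant",
  "inframe_insertion",
  "inframe_deletion"
)

.CONSEQUENCE_CLASSES <- c("pLoF", "missense", "PAV", "none")

#' Classify a variant's transcript consequence
#'
#' Maps a set of sequence-ontology consequence terms (as emitted by VEP on the
#' MANE transcript) to the variant class used for gene-based collapsing:
#' predicted loss-of-function (\code{"pLoF"}: stop gained, frameshift, or
#' essential splice site), \code{"missense"} (missense or in-frame indel), or
#' \code{"none"}. pLoF takes precedence when terms of both kinds are present.
#' Unrecognised terms never error; a term set with no protein-altering term
#' classifies as \code{"none"}.
#'
#' @param terms Character vector of consequence terms for one variant, or a
#'   single comma-joined string.
#' @return One of \code{"pLoF"}, \code{"missense"}, \code{"none"}.
#' @examples
#' classify_consequence("stop_gained")
#' classify_consequence(c("missense_variant", "splice_region_variant"))
#' classify_consequence("synonymous_variant")
#' @export
classify_consequence <- function(terms) {
  stopifnot(length(terms) >= 1L)
  if (length(terms) == 1L && grepl(",", terms, fixed = TRUE)) {
    terms <- strsplit(terms, ",", fixed = TRUE)[[1L]]
  }
  terms <- trimws(terms)
  if (any(terms %in% .PLOF_TERMS)) return("pLoF")
  if (any(terms %in% .MISSENSE_TERMS)) return("missense")
  "none"
}

# Does a variant of class `cls` qualify under a gene rule of class `rule`?
# PAV is exactly the union of pLoF and missense; "none" never qualifies.
class_matches_rule <- function(cls, rule) {
  ifelse(rule == "PAV", cls %in% c("pLoF", "missense"), cls == rule)
}

#' Disease-mechanism gene rules for the twelve definitive DCM genes
#'
#' Each gene is tested on the variant class consistent with its disease
#' mechanism: truncating (pLoF) for \emph{TTN}, \emph{FLNC} and \emph{BAG3};
#' missense for \emph{DES}, \emph{MYH7}, \emph{TNNC1} and \emph{TNNT2};
#' protein-altering (pLoF or missense) for \emph{DSP}, \emph{LMNA},
#' \emph{RBM20}, \emph{SCN5A} and \emph{PLN}. \emph{TTN} additionally requires
#' the variant to hit a constitutively expressed cardiac exon (see
#' \code{\link{passes_ttn_exon_filter}}).
#'
#' @return A data frame with columns \code{gene}, \code{qualifying_class} and
#'   \code{requires_constitutive_exon}.
#' @export
dcm_gene_rules <- function() {
  rules <- data.frame(
    gene = c("TTN", "FLNC", "BAG3",
             "DES", "MYH7", "TNNC1", "TNNT2",
             "DSP", "LMNA", "RBM20", "SCN5A", "PLN"),
    qualifying_class = c("pLoF", "pLoF", "pLoF",
                         "missense", "missense", "missense", "missense",
                         "PAV", "PAV", "PAV", "PAV", "PAV"),
    stringsAsFactors = FALSE
  )
  rules$requires_constitutive_exon <- rules$gene == "TTN"
  rules
}

validate_gene_rules <- function(rules) {
  stopifnot(is.data.frame(rules),
            all(c("gene", "qualifying_class") %in% names(rules)),
            nrow(rules) >= 1L)
  if (anyDuplicated(rules$gene)) {
    stop("gene rules must cover distinct genes")
  }
  bad <- !rules$qualifying_class %in% c("pLoF", "missense", "PAV")
  if (any(bad)) {
    stop("invalid qualifying class for: ",
         paste(rules$gene[bad], collapse = ", "))
  }
  if (is.null(rules$requires_constitutive_exon)) {
    rules$requires_constitutive_exon <- rules$gene == "TTN"
  }
  rules
}
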