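#' Canonical pairwise comparisons
#'
#' The experimental design contrasts three Arabidopsis lines -- wild type
#' (WT), the \emph{fit} knock-out mutant, and the HA-FIT over-expression
#' line -- grown under iron-sufficient (+Fe) or iron-deficient (-Fe)
#' conditions, in two tissues (roots of six-week-old plants, whole six-day-old
#' seedlings).  Seven pairwise comparisons per tissue are used throughout,
#' numbered:
#'
#' \enumerate{
#'   \item fit +Fe vs. WT +Fe
#'   \item fit -Fe vs. WT -Fe
#'   \item HA-FIT +Fe vs. WT +Fe
#'   \item HA-FIT -Fe vs. WT -Fe
#'   \item HA-FIT -Fe vs. HA-FIT +Fe
#'   \item WT -Fe vs. WT +Fe
#'   \item fit -Fe vs. fit +Fe
#' }
#'
#' Comparisons within one line across iron status (5, 6, 7) are
#' \emph{intra-line}; comparisons between lines at fixed iron status
#' (1--4) are \emph{inter-line}.
#'
#' @param tissue `"roots"` or `"seedlings"`.
#' @return A `data.frame` with one row per comparison and columns
#'   `comparison_id`, `number`, `tissue`, `numerator_line`, `numerator_iron`,
#'   `denominator_line`, `denominator_iron`, `comparison_class`.
#' @export
#' @examples
#' canonical_comparisons("roots")
canonical_comparisons <- function(tissue = c("roots", "seedlings")) {
  tissue <- match.arg(tissue)
  spec <- data.frame(
    comparison_id    = paste0("c", 1:7),
    number           = 1:7,
    tissue           = tissue,
    numerator_line   = c("fit", "fit", "HAFIT", "HAFIT", "HAFIT", "WT", "fit"),
    numerator_iron   = c("+Fe", "-Fe", "+Fe", "-Fe", "-Fe", "-Fe", "-Fe"),
    denominator_line = c("WT", "WT", "WT", "WT", "HAFIT", "WT", "fit"),
    denominator_iron = c("+Fe", "-Fe", "+Fe", "-Fe", "+Fe", "+Fe", "+Fe"),
    stringsAsFactors = FALSE
  )
  spec$comparison_class <- ifelse(
    spec$numerator_line == spec$denominator_line, "intra_line", "inter_line")
  validate_comparison_spec(spec)
  spec
}

#' Validate a comparison manifest
#'
#' Checks the structural invariants of a comparison specification table:
#' unique ids, legal line/iron levels, and the intra/inter-line dichotomy
#' (intra-line = same line, different iron; inter-line = different line,
#' same iron).
#'
#' @param spec A `data.frame` as returned by [canonical_comparisons()] or read
#'   from a manifest TSV.
#' @return `spec`, invisibly, after validation.
#' @export
validate_comparison_spec <- function(spec) {
  required <- c("comparison_id", "tissue", "numerator_line", "numerator_iron",
                "denominator_line", "denominator_iron")
  missing <- setdiff(required, names(spec))
  if (length(missing))
    stop("comparison manifest is missing column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(spec$comparison_id))
    stop("duplicate comparison_id in manifest: ",
         paste(unique(spec$comparison_id[duplicated(spec$comparison_id)]),
               collapse = ", "))
  lines <- c("WT", "fit", "HAFIT")
  irons <- c("+Fe", "-Fe")
  if (!all(spec$numerator_line %in% lines) ||
      !all(spec$denominator_line %in% lines))
    stop("line must be one of: ", paste(lines, collapse = ", "))
  if (!all(spec$numerator_iron %in% irons) ||
      !all(spec$denominator_iron %in% irons))
    stop("iron status must be one of: ", paste(irons, collapse = ", "))
  same_line <- spec$numerator_line == spec$denominator_line
  same_iron <- spec$numerator_iron == spec$denominator_iron
  if (any(same_line & same_iron))
    stop("degenerate comparison (same line and iron status): ",
         paste(spec$comparison_id[same_line & same_iron], collapse = ", "))
  if (!is.null(spec$comparison_class)) {
    expect_class <- ifelse(same_line, "intra_line", "inter_line")
    bad <- spec$comparison_class != expect_class
    if (any(bad))
      stop("comparison_class inconsistent with line/iron fields for: ",
           paste(spec$comparison_id[bad], collapse = ", "))
  }
  invisible(spec)
}

#' Normalize AGI gene identifiers
#'
#' Uppercases Arabidopsis Genome Initiative locus codes and strips model
#' version suffixes (e.g. `"at4g19690.1"` becomes `"AT4G19690"`).
#'
#' @param x Character vector of gene identifiers.
#' @return Normalized character vector.
#' @export
normalize_agi <- function(x) {
  sub("\\.\\d+$", "", toupper(trimws(as.character(x))))
}
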