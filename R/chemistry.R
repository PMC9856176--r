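# Residue chemistry classes used to label discriminating-residue calls as
# "similar" or "different". The five-class scheme below is a conventional
# side-chain grouping; it is user-overridable because published colour schemes
# rarely pin the classes down exactly.

#' Default residue chemistry classes
#'
#' Five side-chain classes covering the 20 standard amino acids:
#' nonpolar (G, A, V, L, I, M, P), aromatic (F, W, Y), polar uncharged
#' (S, T, C, N, Q), positively charged (K, R, H) and negatively charged
#' (D, E). Every standard residue belongs to exactly one class.
#'
#' @param overrides Optional named character vector `residue -> class` merged
#'   over the defaults (e.g. `c(H = "aromatic")`).
#' @return Named character vector mapping residue to class label.
#' @export
chemistry_classes <- function(overrides = NULL) {
  cls <- c(
    G = "nonpolar", A = "nonpolar", V = "nonpolar", L = "nonpolar",
    I = "nonpolar", M = "nonpolar", P = "nonpolar",
    F = "aromatic", W = "aromatic", Y = "aromatic",
    S = "polar", T = "polar", C = "polar", N = "polar", Q = "polar",
    K = "positive", R = "positive", H = "positive",
    D = "negative", E = "negative")
  if (!is.null(overrides)) {
    stopifnot(!is.null(names(overrides)))
    cls[names(overrides)] <- overrides
  }
  cls
}

#' Read chemistry classes from a two-column TSV
#'
#' @param path TSV with header columns `residue`, `class`.
#' @return Named character vector as in [chemistry_classes()].
#' @export
read_chemistry_classes <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("residue", "class"), names(tab))
  if (length(miss)) {
    stop("chemistry table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  stats::setNames(as.character(tab$class), toupper(tab$residue))
}

#' Chemistry relation between two residues
#'
#' @param residue_a,residue_b Single-letter residues (vectorised).
#' @param classes Residue class map, see [chemistry_classes()].
#' @return `"similar"` when both residues fall in the same class, otherwise
#'   `"different"`. Residues without a class (e.g. ambiguity codes) yield `NA`.
#' @export
chemistry_relation <- function(residue_a, residue_b,
                               classes = chemistry_classes()) {
  ca <- unname(classes[residue_a])
  cb <- unname(classes[residue_b])
  ifelse(is.na(ca) | is.na(cb), NA_character_,
         ifelse(ca == cb, "similar", "different"))
}
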