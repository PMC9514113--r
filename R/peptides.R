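#' Vaccine peptide specifications
#'
#' A peptide panel is a data frame with one row per vaccine peptide and columns
#' `name`, `sequence`, `k_off` (MHC-I dissociation rate, 1/hour) and
#' `half_life` (hours, `ln 2 / k_off`).  Off-rates may be `NA` when a table is
#' read for bookkeeping only (e.g. the shipped IMA901 peptide list, whose
#' measured half-lives were never published as numbers); peptides entering a
#' simulation must have finite positive off-rates.
#'
#' @param name character vector of peptide identifiers.
#' @param sequence character vector of amino-acid sequences (uppercase
#'   one-letter code, typically 9-mers).
#' @param k_off dissociation rates, 1/hour.  Exactly one of `k_off` and
#'   `half_life` must be given.
#' @param half_life half-lives in hours; converted to `k_off = ln 2 /
#'   half_life`.
#' @return a `peptide_panel` data frame.
#' @examples
#' peptide_panel(c("A", "B"), c("SVASTITGV", "STAPPVHNV"), half_life = c(20, 0.5))
#' @export
peptide_panel <- function(name, sequence, k_off = NULL, half_life = NULL) {
  if (is.null(k_off) == is.null(half_life))
    stopf("give exactly one of `k_off` and `half_life`")
  if (is.null(k_off)) k_off <- log(2) / half_life
  half_life <- log(2) / k_off
  pan <- data.frame(name = as.character(name),
                    sequence = toupper(as.character(sequence)),
                    k_off = as.numeric(k_off),
                    half_life = as.numeric(half_life),
                    stringsAsFactors = FALSE)
  class(pan) <- c("peptide_panel", "data.frame")
  validate_peptide_panel(pan)
}

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' @rdname peptide_panel
#' @param pan a `peptide_panel`.
#' @export
validate_peptide_panel <- function(pan) {
  if (nrow(pan) == 0) stopf("peptide panel is empty")
  if (anyDuplicated(pan$name)) stopf("duplicate peptide names")
  if (any(!nzchar(pan$sequence)))
    stopf("peptide sequences must be non-empty")
  bad <- !grepl(sprintf("^[%s]+$", paste(AA_ALPHABET, collapse = "")),
                pan$sequence)
  if (any(bad))
    stopf("invalid amino-acid sequence for: %s",
          paste(pan$name[bad], collapse = ", "))
  known <- !is.na(pan$k_off)
  if (any(pan$k_off[known] < 0))
    stopf("k_off must be > 0 (peptide %s)",
          paste(pan$name[known][pan$k_off[known] < 0], collapse = ", "))
  # k_off = 0 (no dissociation, half_life = Inf) is admitted for limit cases.
  pos <- known & pan$k_off > 0
  rel <- abs(pan$half_life[pos] * pan$k_off[pos] - log(2)) / log(2)
  if (any(rel > 1e-9))
    stopf("half_life and k_off inconsistent (half_life * k_off != ln 2)")
  if (any(known & pan$k_off == 0 & !is.infinite(pan$half_life)))
    stopf("k_off = 0 requires half_life = Inf")
  invisible(pan)
}

require_rates <- function(pan) {
  if (any(is.na(pan$k_off)))
    stopf("peptide(s) without off-rates cannot be simulated: %s",
          paste(pan$name[is.na(pan$k_off)], collapse = ", "))
  invisible(pan)
}

#' Read / write a peptide table
#'
#' The on-disk format is CSV with header `name,sequence,half_life_h` or
#' `name,sequence,k_off_per_h`; exactly one of the two rate columns must be
#' present.  Blank rate entries become `NA` (peptides that cannot be simulated
#' until rates are supplied, e.g. with [set_half_lives()]).
#'
#' @param path file path.
#' @return [read_peptide_table()] returns a `peptide_panel`;
#'   [write_peptide_table()] returns `path` invisibly.
#' @examples
#' p <- read_peptide_table(system.file("extdata", "ima901_peptides.csv",
#'                                     package = "pepvax"))
#' nrow(p)  # 9 tumour-associated peptides
#' @export
read_peptide_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  has_hl <- "half_life_h" %in% names(tab)
  has_ko <- "k_off_per_h" %in% names(tab)
  if (has_hl == has_ko)
    stopf("peptide table must have exactly one of `half_life_h`, `k_off_per_h`")
  if (!all(c("name", "sequence") %in% names(tab)))
    stopf("peptide table must have `name` and `sequence` columns")
  if (has_hl)
    peptide_panel(tab$name, tab$sequence,
                  half_life = as.numeric(tab$half_life_h))
  else
    peptide_panel(tab$name, tab$sequence,
                  k_off = as.numeric(tab$k_off_per_h))
}

#' @rdname read_peptide_table
#' @param pan a `peptide_panel`.
#' @export
write_peptide_table <- function(pan, path) {
  validate_peptide_panel(pan)
  out <- data.frame(name = pan$name, sequence = pan$sequence,
                    half_life_h = pan$half_life)
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Replace the half-lives of a peptide panel
#'
#' @param pan a `peptide_panel`.
#' @param half_life hours; recycled named by `names(half_life)` if named,
#'   otherwise positional.
#' @return the updated panel.
#' @export
set_half_lives <- function(pan, half_life) {
  if (!is.null(names(half_life))) {
    idx <- match(names(half_life), pan$name)
    if (anyNA(idx)) stopf("unknown peptide name(s): %s",
                          paste(names(half_life)[is.na(idx)], collapse = ", "))
    pan$half_life[idx] <- as.numeric(half_life)
  } else {
    if (length(half_life) != nrow(pan))
      stopf("need %d half-lives, got %d", nrow(pan), length(half_life))
    pan$half_life <- as.numeric(half_life)
  }
  pan$k_off <- log(2) / pan$half_life
  validate_peptide_panel(pan)
}
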