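#' Reverse complement
#'
#' Vectorised reverse complement over the alphabet `{A, C, G, T, N}`;
#' `N` maps to `N`. An involution: `revcomp(revcomp(x)) == x`.
#'
#' @param x Character vector of DNA sequences (upper case).
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp(c("ACGTN", "GATTACA"))
revcomp <- function(x) {
  stopifnot(is.character(x))
  if (length(x) == 0L) return(character(0))
  .revcomp_cpp(x)
}

# Abort with a classed condition so tests can target error families.
abort_overbin <- function(msg, class) {
  stop(structure(
    class = c(class, "overbin_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

config_error <- function(msg) abort_overbin(msg, "overbin_config_error")
contract_error <- function(msg) abort_overbin(msg, "overbin_contract_error")
parse_error <- function(msg) abort_overbin(msg, "overbin_parse_error")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Biostrings warns about dropping (empty) metadata columns when
# converting between XStringSet flavours; that is noise here.
quiet_mcols <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("metadata columns", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

# Normalise and validate a DNA sequence vector.
normalize_dna <- function(x, what = "sequence") {
  x <- toupper(x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    contract_error(sprintf(
      "%s %d contains characters outside {A,C,G,T,N}", what, which(bad)[1]
    ))
  }
  x
}
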