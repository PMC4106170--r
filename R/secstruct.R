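#' Reduce an 8-state DSSP secondary-structure string to 3 states
#'
#' Applies the standard DSSP reduction: \code{H}, \code{G}, \code{I}
#' (alpha-, 3-10- and pi-helix) map to \code{H}; \code{E}, \code{B}
#' (strand and isolated bridge) map to \code{E}; everything else
#' (\code{T}, \code{S}, blank, \code{-}) maps to \code{C}. The mapping is
#' configurable; any map must cover the 8-state alphabet and target only
#' \code{H}/\code{E}/\code{C}.
#'
#' @param dssp_string character string over the 8-state DSSP alphabet
#'   \code{H G I E B T S -} plus blank.
#' @param map named character vector giving the reduction.
#' @return a string of the same length over \code{H}, \code{E}, \code{C}.
#' @examples
#' reduce_8_to_3("HGIEBTS-")  # "HHHEECCC"
#' @export
reduce_8_to_3 <- function(dssp_string,
                          map = c(H = "H", G = "H", I = "H",
                                  E = "E", B = "E",
                                  T = "C", S = "C", "-" = "C", " " = "C")) {
  stopifnot(is.character(dssp_string), length(dssp_string) == 1L)
  if (!all(map %in% acs_ss_states())) {
    stop("reduction map must target only H, E, C")
  }
  if (nchar(dssp_string) == 0L) return("")
  chars <- strsplit(dssp_string, "", fixed = TRUE)[[1]]
  # already-reduced strings pass through unchanged (idempotence)
  out <- ifelse(chars %in% acs_ss_states() & !(chars %in% names(map)),
                chars, unname(map[chars]))
  bad <- which(is.na(out))
  if (length(bad)) {
    stop("character '", chars[bad[1L]], "' at position ", bad[1L],
         " is outside the 8-state secondary-structure alphabet")
  }
  paste(out, collapse = "")
}

#' Validate a secondary-structure string against its sequence
#'
#' Checks that \code{ss} and \code{sequence} have equal length and that
#' every SS character is one of \code{H}, \code{E}, \code{C}.
#'
#' @param ss three-state secondary-structure string.
#' @param sequence amino-acid sequence string.
#' @param record optional record name used in error messages.
#' @return invisibly, a list with the checked \code{sequence} and \code{ss}.
#' @export
validate_ss <- function(ss, sequence, record = NULL) {
  tag <- if (is.null(record)) "" else paste0(" in record '", record, "'")
  if (nchar(ss) != nchar(sequence)) {
    stop("secondary-structure length (", nchar(ss),
         ") does not match sequence length (", nchar(sequence), ")", tag)
  }
  chars <- strsplit(ss, "", fixed = TRUE)[[1]]
  bad <- which(!(chars %in% acs_ss_states()))
  if (length(bad)) {
    stop("secondary-structure character '", chars[bad[1L]],
         "' at position ", bad[1L], tag, "; allowed: H, E, C")
  }
  invisible(list(sequence = sequence, ss = ss))
}

#' Validate a protein sample data frame
#'
#' @param samples data frame with columns \code{protein_id}, \code{sequence},
#'   \code{ss}.
#' @return the validated data frame, invisibly.
#' @keywords internal
.validate_samples <- function(samples) {
  need <- c("protein_id", "sequence", "ss")
  if (!all(need %in% names(samples))) {
    stop("samples must have columns ", paste(need, collapse = ", "))
  }
  for (r in seq_len(nrow(samples))) {
    validate_ss(samples$ss[r], samples$sequence[r],
                record = samples$protein_id[r])
  }
  invisible(samples)
}
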