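#' Atom-label dialect for chemical-shift files
#'
#' Chemical-shift files label backbone atoms with raw spectroscopic names
#' (\code{"N"}, \code{"CA"}, \code{"HA"}, \code{"H"}, ...). A dialect maps
#' those labels onto the four atom kinds the package tracks. The default map
#' sends \code{N} to \code{N15}, \code{CA} to \code{C13A}, \code{HA} (and
#' glycine's stereo pair \code{HA2}/\code{HA3}) to \code{H1A}, and \code{H} /
#' \code{HN} to \code{H1N}. Both glycine alpha-protons are kept as Halpha
#' observations: dropping one would bias the glycine cell.
#'
#' @param atom_name_map named character vector: names are raw labels as they
#'   appear in the file, values are atom kinds (see [acs_atoms()]).
#' @param skip_unmapped if \code{TRUE} (default) rows whose atom label is not
#'   in the map are skipped and counted in the parse report; if \code{FALSE}
#'   an unmapped label is an error.
#' @return an object of class \code{shift_dialect}.
#' @export
shift_dialect <- function(atom_name_map = c(N = "N15", CA = "C13A",
                                            HA = "H1A", HA2 = "H1A",
                                            HA3 = "H1A", H = "H1N",
                                            HN = "H1N"),
                          skip_unmapped = TRUE) {
  if (is.null(names(atom_name_map)) || any(names(atom_name_map) == "")) {
    stop("atom_name_map must be a fully named character vector")
  }
  .check_atom(unname(atom_name_map))
  structure(list(atom_name_map = atom_name_map,
                 skip_unmapped = isTRUE(skip_unmapped)),
            class = "shift_dialect")
}

# required loop tags, in canonical order
.shift_tags <- c("_Atom_chem_shift.Seq_ID", "_Atom_chem_shift.Comp_ID",
                 "_Atom_chem_shift.Atom_ID", "_Atom_chem_shift.Val")

.read_text <- function(path_or_text) {
  if (length(path_or_text) == 1L && !grepl("\n", path_or_text) &&
      file.exists(path_or_text)) {
    readLines(path_or_text, warn = FALSE)
  } else {
    unlist(strsplit(paste(path_or_text, collapse = "\n"), "\n", fixed = TRUE))
  }
}

#' Parse a minimal NMR-STAR-style chemical-shift document
#'
#' Reads assigned per-residue backbone chemical shifts from a star-like text
#' document: one save-frame per protein, each holding one \code{loop_} whose
#' tags include residue index, residue name (1- or 3-letter), atom label and
#' shift value in ppm. Only this minimal subset of the NMR-STAR grammar is
#' supported.
#'
#' @param path_or_text a file path or the document text itself.
#' @param dialect a [shift_dialect()] mapping raw atom labels to atom kinds.
#' @param strict if \code{TRUE} (default) a malformed row (non-numeric shift,
#'   unknown residue name) raises an error naming the line; if \code{FALSE}
#'   such rows are collected in the parse report instead.
#' @param sanity_bounds if \code{TRUE}, warn when a shift falls outside
#'   plausible ppm ranges (\[0, 250\] for N15/C13A, \[-2, 15\] for protons);
#'   rows are never dropped for this. Default \code{FALSE}.
#' @return a data frame of observations with columns \code{protein_id},
#'   \code{residue_index}, \code{residue}, \code{atom}, \code{shift_ppm},
#'   carrying a \code{"report"} attribute (see [parse_report()]).
#' @seealso [write_shift_file()], [parse_report()]
#' @export
parse_shift_file <- function(path_or_text, dialect = shift_dialect(),
                             strict = TRUE, sanity_bounds = FALSE) {
  stopifnot(inherits(dialect, "shift_dialect"))
  lines <- .read_text(path_or_text)
  trimmed <- trimws(lines)

  save_starts <- grep("^save_.+", trimmed)
  if (length(save_starts) == 0L) {
    # tolerate a bare loop with no save-frame: single anonymous protein
    save_starts <- integer(0)
  }
  loop_starts <- grep("^loop_$", trimmed)
  if (length(loop_starts) == 0L) {
    stop("no chemical-shift loop_ found in document")
  }

  rows <- list()
  n_skipped <- 0L
  n_errored <- 0L
  messages <- character(0)

  for (ls in loop_starts) {
    # protein id = nearest preceding save_ frame name
    prev <- save_starts[save_starts < ls]
    pid <- if (length(prev)) sub("^save_", "", trimmed[max(prev)]) else "protein_1"

    # read tags
    i <- ls + 1L
    tags <- character(0)
    while (i <= length(trimmed) && startsWith(trimmed[i], "_")) {
      tags <- c(tags, trimmed[i])
      i <- i + 1L
    }
    missing_tags <- setdiff(.shift_tags, tags)
    if (length(missing_tags)) {
      stop("malformed shift loop (line ", ls, "): missing column(s) ",
           paste(missing_tags, collapse = ", "))
    }
    col <- match(.shift_tags, tags)

    # data rows until stop_
    j <- i
    while (j <= length(trimmed) && trimmed[j] != "stop_") j <- j + 1L
    if (j > length(trimmed)) stop("unterminated loop_ at line ", ls)
    data_idx <- setdiff(seq.int(i, j - 1L), which(trimmed == ""))
    data_idx <- data_idx[nzchar(trimmed[data_idx])]
    if (!length(data_idx)) next

    fields <- strsplit(trimmed[data_idx], "[ \t]+")
    nf <- lengths(fields)
    bad_nf <- nf < length(tags)
    if (any(bad_nf)) {
      msg <- paste0("line ", data_idx[bad_nf], ": expected ", length(tags),
                    " fields, found ", nf[bad_nf])
      if (strict) stop(msg[1L])
      n_errored <- n_errored + sum(bad_nf)
      messages <- c(messages, msg)
      fields <- fields[!bad_nf]
      data_idx <- data_idx[!bad_nf]
      if (!length(fields)) next
    }
    m <- do.call(rbind, fields)
    seq_id <- suppressWarnings(as.integer(m[, col[1L]]))
    res_raw <- m[, col[2L]]
    atom_raw <- m[, col[3L]]
    val <- suppressWarnings(as.numeric(m[, col[4L]]))

    bad_val <- is.na(val)
    if (any(bad_val)) {
      msg <- paste0("line ", data_idx[bad_val], ": non-numeric shift value '",
                    m[bad_val, col[4L]], "'")
      if (strict) stop(msg[1L])
      n_errored <- n_errored + sum(bad_val)
      messages <- c(messages, msg)
    }
    res <- .normalize_residue(res_raw)
    bad_res <- is.na(res) & !bad_val
    if (any(bad_res)) {
      msg <- paste0("line ", data_idx[bad_res], ": unknown residue name '",
                    res_raw[bad_res], "'")
      if (strict) stop(msg[1L])
      n_errored <- n_errored + sum(bad_res)
      messages <- c(messages, msg)
    }
    ok <- !bad_val & !bad_res

    atom <- unname(dialect$atom_name_map[atom_raw])
    unmapped <- is.na(atom) & ok
    if (any(unmapped) && !dialect$skip_unmapped) {
      stop("line ", data_idx[unmapped][1L], ": unmapped atom label '",
           atom_raw[unmapped][1L], "'")
    }
    n_skipped <- n_skipped + sum(unmapped)
    keep <- ok & !unmapped
    if (any(keep)) {
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = pid, residue_index = seq_id[keep],
        residue = res[keep], atom = atom[keep], shift_ppm = val[keep],
        stringsAsFactors = FALSE)
    }
  }

  obs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(protein_id = character(0), residue_index = integer(0),
               residue = character(0), atom = character(0),
               shift_ppm = numeric(0), stringsAsFactors = FALSE)
  rownames(obs) <- NULL

  if (sanity_bounds && nrow(obs)) {
    heavy <- obs$atom %in% c("N15", "C13A")
    out_of_band <- (heavy & (obs$shift_ppm < 0 | obs$shift_ppm > 250)) |
      (!heavy & (obs$shift_ppm < -2 | obs$shift_ppm > 15))
    if (any(out_of_band)) {
      warning(sum(out_of_band),
              " shift value(s) outside plausible ppm bounds (kept)")
    }
  }

  attr(obs, "report") <- list(accepted = nrow(obs), skipped = n_skipped,
                              errored = n_errored, messages = messages)
  obs
}

#' Extract the parse report from a parsed observation set
#'
#' @param observations the data frame returned by [parse_shift_file()].
#' @return a list with counts \code{accepted}, \code{skipped},
#'   \code{errored} and a character vector \code{messages}.
#' @export
parse_report <- function(observations) {
  rep <- attr(observations, "report")
  if (is.null(rep)) stop("object carries no parse report")
  rep
}

#' Write chemical-shift observations as a star-like document
#'
#' Inverse of [parse_shift_file()]: observations are grouped by protein into
#' one save-frame each, with atom kinds written back under their canonical
#' labels (\code{N}, \code{CA}, \code{HA}, \code{H}) and shifts printed at
#' full double precision so that a parse/write cycle is the identity.
#'
#' @param observations data frame with columns \code{protein_id},
#'   \code{residue_index}, \code{residue}, \code{atom}, \code{shift_ppm}.
#' @param path optional file path; when \code{NULL} the document text is
#'   returned invisibly as a character scalar.
#' @return the document text, invisibly when written to \code{path}.
#' @export
write_shift_file <- function(observations, path = NULL) {
  if (is.null(observations) || nrow(observations) == 0L) {
    stop("observations must be non-empty")
  }
  .check_atom(observations$atom)
  canonical <- c(N15 = "N", C13A = "CA", H1A = "HA", H1N = "H")
  out <- c("data_chemical_shifts", "")
  for (pid in unique(observations$protein_id)) {
    g <- observations[observations$protein_id == pid, , drop = FALSE]
    out <- c(out,
             paste0("save_", pid),
             "loop_",
             paste0("  ", .shift_tags),
             sprintf("  %d %s %s %s",
                     g$residue_index,
                     .aa1to3[g$residue],
                     canonical[g$atom],
                     sprintf("%.17g", g$shift_ppm)),
             "stop_",
             "save_",
             "")
  }
  text <- paste(out, collapse = "\n")
  if (!is.null(path)) {
    writeLines(text, path)
    return(invisible(text))
  }
  text
}

#' Export observations as TSV
#'
#' @param observations data frame of shift observations.
#' @param path file path.
#' @export
write_shift_tsv <- function(observations, path) {
  utils::write.table(observations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Parse paired sequence / secondary-structure text
#'
#' Reads the one-line paired dialect: each record is an optional
#' \code{">"}-header line, then the full amino-acid sequence on a single
#' line, then its aligned three-state secondary-structure string (over
#' \code{H}, \code{E}, \code{C}) on the next line. No line wrapping.
#'
#' @param path_or_text file path or the text itself.
#' @return a data frame of protein samples with columns \code{protein_id},
#'   \code{sequence}, \code{ss}.
#' @seealso [read_fasta_pair()] for FASTA sequences with a parallel SS file.
#' @export
parse_paired_sequence_ss <- function(path_or_text) {
  lines <- .read_text(path_or_text)
  lines <- lines[nzchar(trimws(lines))]
  lines <- trimws(lines)

  ids <- character(0); seqs <- character(0); sss <- character(0)
  i <- 1L
  n_anon <- 0L
  while (i <= length(lines)) {
    id <- NULL
    if (startsWith(lines[i], ">")) {
      id <- sub("^>\\s*", "", lines[i])
      i <- i + 1L
      if (i > length(lines)) stop("header '", id, "' has no sequence line")
    }
    if (is.null(id)) {
      n_anon <- n_anon + 1L
      id <- paste0("protein_", length(ids) + 1L)
    }
    if (i + 1L > length(lines)) {
      stop("record '", id, "': sequence line has no secondary-structure line")
    }
    seqs <- c(seqs, toupper(lines[i]))
    sss <- c(sss, toupper(lines[i + 1L]))
    ids <- c(ids, id)
    i <- i + 2L
  }

  for (r in seq_along(ids)) {
    validate_ss(sss[r], seqs[r], record = ids[r])
  }
  data.frame(protein_id = ids, sequence = seqs, ss = sss,
             stringsAsFactors = FALSE)
}

#' Read sequences from FASTA with secondary structure in a parallel file
#'
#' The FASTA file supplies the sequences (wrapped lines allowed, read via
#' Biostrings); the SS file is a second FASTA-like file whose records, in
#' the same order or matched by header, carry the aligned H/E/C strings.
#'
#' @param fasta_path path to the sequence FASTA.
#' @param ss_path path to the secondary-structure FASTA.
#' @return a protein-sample data frame as in [parse_paired_sequence_ss()].
#' @export
read_fasta_pair <- function(fasta_path, ss_path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("read_fasta_pair requires the Biostrings package")
  }
  seqs <- Biostrings::readBStringSet(fasta_path)
  sss <- Biostrings::readBStringSet(ss_path)
  sid <- sub("\\s.*$", "", names(seqs))
  kid <- sub("\\s.*$", "", names(sss))
  idx <- if (all(sid %in% kid)) match(sid, kid) else seq_along(sss)
  if (length(seqs) != length(sss)) {
    stop("sequence and secondary-structure files differ in record count (",
         length(seqs), " vs ", length(sss), ")")
  }
  out <- data.frame(protein_id = sid,
                    sequence = unname(toupper(as.character(seqs))),
                    ss = unname(toupper(as.character(sss[idx]))),
                    stringsAsFactors = FALSE, row.names = NULL)
  rownames(out) <- NULL
  for (r in seq_len(nrow(out))) {
    validate_ss(out$ss[r], out$sequence[r], record = out$protein_id[r])
  }
  out
}
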