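#' Curate a shift corpus before table building
#'
#' Applies the benchmark curation filters to an observation set: proteins
#' shorter than \code{min_length} residues, and proteins with no
#' SS-annotated sample, are removed together with all their observations.
#' Filtering is total: nothing errors, everything removed is counted.
#'
#' @param observations shift-observation data frame (see
#'   [parse_shift_file()]).
#' @param samples protein-sample data frame with \code{protein_id},
#'   \code{sequence}, \code{ss}.
#' @param min_length minimum sequence length retained; default 50.
#' @return the retained observations, with a \code{"curation"} attribute:
#'   a list with \code{n_short}, \code{n_unmatched}, \code{removed} (a data
#'   frame of protein_id and reason).
#' @export
curate_observations <- function(observations, samples, min_length = 50L) {
  .validate_samples(samples)
  obs_pids <- unique(observations$protein_id)
  slen <- structure(nchar(samples$sequence), names = samples$protein_id)

  unmatched <- obs_pids[!(obs_pids %in% samples$protein_id)]
  matched <- setdiff(obs_pids, unmatched)
  short <- matched[slen[matched] < min_length]
  keep <- setdiff(matched, short)

  removed <- rbind(
    if (length(short)) data.frame(protein_id = short, reason = "short",
                                  stringsAsFactors = FALSE),
    if (length(unmatched)) data.frame(protein_id = unmatched,
                                      reason = "unmatched",
                                      stringsAsFactors = FALSE))
  if (is.null(removed)) {
    removed <- data.frame(protein_id = character(0), reason = character(0),
                          stringsAsFactors = FALSE)
  }
  out <- observations[observations$protein_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "curation") <- list(n_short = length(short),
                                n_unmatched = length(unmatched),
                                removed = removed)
  out
}

# pairwise sequence identity: exact-match fraction over a global
# (Needleman-Wunsch) alignment
.pair_identity <- function(a, b) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("identity_filter requires the Biostrings package")
  }
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global")
  Biostrings::pid(aln, type = "PID1") / 100
}

#' Redundancy filter on protein samples
#'
#' Greedy longest-first clustering in the spirit of CD-HIT: samples are
#' visited in decreasing length order and a sample is rejected when its
#' pairwise identity to any already-retained sample exceeds
#' \code{max_identity}. Identity is the exact-match fraction over a global
#' alignment. This is a deliberate simplification — it makes a
#' redundancy-screened pipeline runnable end to end, and does not reproduce
#' CD-HIT's word-filter heuristics.
#'
#' @param samples protein-sample data frame.
#' @param max_identity identity threshold above which a sample is rejected;
#'   default 0.40.
#' @return the retained samples, in the original input order.
#' @export
identity_filter <- function(samples, max_identity = 0.40) {
  if (nrow(samples) < 1L) stop("at least one sample required")
  ord <- order(-nchar(samples$sequence), seq_len(nrow(samples)))
  retained <- integer(0)
  for (i in ord) {
    redundant <- FALSE
    for (j in retained) {
      if (.pair_identity(samples$sequence[i], samples$sequence[j]) >
          max_identity) {
        redundant <- TRUE
        break
      }
    }
    if (!redundant) retained <- c(retained, i)
  }
  out <- samples[sort(retained), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# the fixed 240-row cell grid, in canonical order:
# atom (N15, C13A, H1A, H1N), residue alphabetical, ss (H, E, C)
.empty_grid <- function() {
  g <- expand.grid(ss = acs_ss_states(), residue = acs_residues(),
                   atom = acs_atoms(), stringsAsFactors = FALSE,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("atom", "residue", "ss")]
  g$atom <- factor(g$atom, levels = acs_atoms())
  g <- g[order(g$atom, g$residue, match(g$ss, acs_ss_states())), ]
  g$atom <- as.character(g$atom)
  rownames(g) <- NULL
  g
}

.cell_key <- function(atom, residue, ss) paste(atom, residue, ss, sep = "|")

#' Build an averaged-chemical-shift (ACS) table
#'
#' The core statistic: for every backbone atom kind i, residue type j and
#' three-state secondary-structure state k, the cell value is the arithmetic
#' mean of all chemical shifts observed for that combination, pooled over
#' all proteins:
#' \deqn{C_k^i(j) = \frac{1}{N}\sum_N \omega_k^i(j)}
#' with N the number of contributing observations. Each observation is
#' routed to its cell by looking up the residue and SS state at its
#' (protein, position) in \code{samples}. The result is the full
#' 4 x 20 x 3 = 240-cell grid; cells with no observations (notably proline's
#' amide proton, which does not exist) are kept with count 0 and flagged
#' missing rather than dropped.
#'
#' @param observations shift-observation data frame, typically the output of
#'   [curate_observations()].
#' @param samples SS-annotated protein samples covering every protein_id in
#'   \code{observations}.
#' @param provenance free-text build metadata stored on the table.
#' @return an object of class \code{acs_table}: a 240-row data frame with
#'   columns \code{atom}, \code{residue}, \code{ss}, \code{mean_ppm},
#'   \code{count}, \code{sd_ppm} in fixed row order.
#' @seealso [predict.acs_table()] for encoding, [write_acs_table()] /
#'   [read_acs_table()] for serialization.
#' @export
build_acs_table <- function(observations, samples, provenance = "") {
  .validate_samples(samples)
  sidx <- match(observations$protein_id, samples$protein_id)
  if (anyNA(sidx)) {
    stop("observation references unknown protein '",
         observations$protein_id[which(is.na(sidx))[1L]], "'")
  }
  L <- nchar(samples$sequence)[sidx]
  over <- which(observations$residue_index > L |
                  observations$residue_index < 1L)
  if (length(over)) {
    k <- over[1L]
    stop("observation index ", observations$residue_index[k],
         " is outside protein '", observations$protein_id[k],
         "' (length ", L[k], ")")
  }
  seq_res <- substr(samples$sequence[sidx],
                    observations$residue_index, observations$residue_index)
  disagree <- which(seq_res != observations$residue)
  if (length(disagree)) {
    k <- disagree[1L]
    stop("residue mismatch in protein '", observations$protein_id[k],
         "' position ", observations$residue_index[k],
         ": observation says ", observations$residue[k],
         ", sequence says ", seq_res[k])
  }
  ss <- substr(samples$ss[sidx],
               observations$residue_index, observations$residue_index)

  key <- .cell_key(observations$atom, observations$residue, ss)
  grid <- .empty_grid()
  gkey <- .cell_key(grid$atom, grid$residue, grid$ss)

  agg_mean <- tapply(observations$shift_ppm, key, mean)
  agg_n <- tapply(observations$shift_ppm, key, length)
  agg_sd <- tapply(observations$shift_ppm, key, stats::sd)

  pos <- match(gkey, names(agg_mean))
  grid$mean_ppm <- as.numeric(agg_mean[pos])
  grid$count <- ifelse(is.na(pos), 0L, as.integer(agg_n[pos]))
  grid$sd_ppm <- as.numeric(agg_sd[pos])
  grid$sd_ppm[grid$count == 1L] <- 0
  grid$sd_ppm[grid$count == 0L] <- NA_real_
  grid$mean_ppm[grid$count == 0L] <- NA_real_

  structure(grid, provenance = provenance,
            class = c("acs_table", "data.frame"))
}

#' @export
print.acs_table <- function(x, ...) {
  n_missing <- sum(x$count == 0L)
  cat("Averaged chemical shift (ACS) table\n")
  cat("  240 cells: 4 atoms x 20 residues x 3 secondary-structure states\n")
  cat("  observations: ", sum(x$count), "; missing cells: ", n_missing,
      "\n", sep = "")
  prov <- attr(x, "provenance")
  if (!is.null(prov) && nzchar(prov)) cat("  provenance: ", prov, "\n",
                                          sep = "")
  invisible(x)
}

#' @export
summary.acs_table <- function(object, ...) {
  by_atom <- lapply(split(object, object$atom), function(g) {
    c(n_obs = sum(g$count),
      n_missing = sum(g$count == 0L),
      mean_ppm = mean(g$mean_ppm, na.rm = TRUE),
      min_ppm = suppressWarnings(min(g$mean_ppm, na.rm = TRUE)),
      max_ppm = suppressWarnings(max(g$mean_ppm, na.rm = TRUE)))
  })
  out <- do.call(rbind, by_atom)[acs_atoms(), , drop = FALSE]
  structure(out, class = c("summary.acs_table", class(out)))
}

#' Flag missing table cells
#'
#' @param table an \code{acs_table}.
#' @return logical vector over the 240 rows, \code{TRUE} where no
#'   observation reached the cell.
#' @export
missing_cells <- function(table) {
  stopifnot(inherits(table, "acs_table"))
  table$count == 0L
}

#' Serialize an ACS table to TSV
#'
#' Writes the 240-cell grid as tab-separated text with columns atom,
#' residue, ss, mean_ppm, count, sd_ppm in the canonical row order. Numeric
#' fields are printed at full double precision so the round-trip through
#' [read_acs_table()] is lossless.
#'
#' @param table an \code{acs_table}.
#' @param path file path.
#' @export
write_acs_table <- function(table, path) {
  stopifnot(inherits(table, "acs_table"))
  df <- as.data.frame(table)
  df$mean_ppm <- ifelse(is.na(df$mean_ppm), "NA",
                        sprintf("%.17g", df$mean_ppm))
  df$sd_ppm <- ifelse(is.na(df$sd_ppm), "NA", sprintf("%.17g", df$sd_ppm))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an ACS table from TSV
#'
#' Keys absent from the file become missing cells (count 0); a duplicated
#' key is an error.
#'
#' @param path file path to a TSV written by [write_acs_table()] (subsets
#'   of the grid are allowed).
#' @return an \code{acs_table}.
#' @export
read_acs_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(atom = "character",
                                         residue = "character",
                                         ss = "character"))
  need <- c("atom", "residue", "ss", "mean_ppm", "count", "sd_ppm")
  if (!all(need %in% names(df))) {
    stop("ACS table file must have columns ", paste(need, collapse = ", "))
  }
  .check_atom(df$atom)
  key <- .cell_key(df$atom, df$residue, df$ss)
  if (anyDuplicated(key)) {
    stop("duplicate cell key in table file: ", key[duplicated(key)][1L])
  }
  grid <- .empty_grid()
  pos <- match(.cell_key(grid$atom, grid$residue, grid$ss), key)
  grid$mean_ppm <- df$mean_ppm[pos]
  grid$count <- ifelse(is.na(pos), 0L, df$count[pos])
  grid$sd_ppm <- df$sd_ppm[pos]
  grid$mean_ppm[grid$count == 0L] <- NA_real_
  grid$sd_ppm[grid$count == 0L] <- NA_real_
  structure(grid, provenance = paste0("read from ", path),
            class = c("acs_table", "data.frame"))
}
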