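#' Replace a protein's residues with their averaged chemical shifts
#'
#' Builds the per-position shift series for one atom kind: position l of the
#' series is the ACS table cell mean for (atom, residue at l, SS state at l).
#' A lookup can hit a missing cell — proline has no amide proton, and a
#' sparsely populated table may have empty cells — and the missing-cell
#' policy decides what happens: \code{"error"} raises naming the cell,
#' \code{"cell_row_mean"} substitutes the count-weighted mean of the same
#' (atom, residue) over the SS states that do have data (falling back to the
#' atom-wide count-weighted mean), and \code{"zero"} substitutes 0. Missing
#' positions are recorded regardless of policy.
#'
#' @param sequence amino-acid sequence string.
#' @param ss aligned three-state secondary-structure string.
#' @param table an \code{acs_table}.
#' @param atom one atom kind (see [acs_atoms()]).
#' @param missing_policy one of \code{"cell_row_mean"}, \code{"error"},
#'   \code{"zero"}.
#' @param nonstandard what to do with residues outside the 20-letter
#'   alphabet: \code{"error"} (default, lists the positions) or
#'   \code{"average"} (use the atom/SS-matched residue-averaged value).
#' @param protein_id optional name used in error messages.
#' @return numeric vector of length \code{nchar(sequence)} with attribute
#'   \code{"missing_positions"}.
#' @export
acs_series <- function(sequence, ss, table, atom,
                       missing_policy = c("cell_row_mean", "error", "zero"),
                       nonstandard = c("error", "average"),
                       protein_id = "protein") {
  missing_policy <- match.arg(missing_policy)
  nonstandard <- match.arg(nonstandard)
  stopifnot(inherits(table, "acs_table"), length(atom) == 1L)
  .check_atom(atom)
  validate_ss(ss, sequence, record = protein_id)

  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  kst <- strsplit(ss, "", fixed = TRUE)[[1]]
  L <- length(res)

  odd <- which(!(res %in% acs_residues()))
  if (length(odd) && nonstandard == "error") {
    stop("non-standard residue(s) in '", protein_id, "' at position(s) ",
         paste(odd, collapse = ", "), " (",
         paste(unique(res[odd]), collapse = ", "),
         "); use nonstandard = \"average\" to encode them anyway")
  }

  tk <- .cell_key(table$atom, table$residue, table$ss)
  pos <- match(.cell_key(atom, res, kst), tk)
  vals <- table$mean_ppm[pos]   # NA where cell missing or residue unknown

  at_rows <- table$atom == atom
  atom_wide <- stats::weighted.mean(table$mean_ppm[at_rows],
                                    table$count[at_rows], na.rm = TRUE)

  if (length(odd)) {
    # residue-averaged cell value for the matching (atom, ss)
    for (l in odd) {
      rows <- at_rows & table$ss == kst[l] & table$count > 0L
      vals[l] <- if (any(rows)) {
        stats::weighted.mean(table$mean_ppm[rows], table$count[rows])
      } else atom_wide
    }
  }

  miss <- setdiff(which(is.na(vals)), odd)
  if (length(miss)) {
    if (missing_policy == "error") {
      l <- miss[1L]
      stop("missing ACS cell (", atom, ", ", res[l], ", ", kst[l],
           ") needed by '", protein_id, "' at position ", l)
    }
    if (missing_policy == "zero") {
      vals[miss] <- 0
    } else {
      for (l in miss) {
        rows <- at_rows & table$residue == res[l] & table$count > 0L
        vals[l] <- if (any(rows)) {
          stats::weighted.mean(table$mean_ppm[rows], table$count[rows])
        } else atom_wide
      }
    }
  }
  structure(vals, missing_positions = miss)
}

#' Lagged mean squared difference of a shift series
#'
#' The series summary at lag lambda:
#' \deqn{\theta(\lambda) = \frac{1}{L-\lambda}
#'       \sum_{l=1}^{L-\lambda} (S_l - S_{l+\lambda})^2}
#' a variogram-style statistic: nonnegative, zero exactly when the series is
#' lag-lambda periodic, invariant to adding a constant, and scaling the
#' series by a multiplies it by a squared. Valid lags are 0 < lambda < L.
#'
#' @param series numeric shift series.
#' @param lam integer lag.
#' @return the scalar theta(lambda).
#' @export
acs_theta <- function(series, lam) {
  L <- length(series)
  if (lam <= 0L || lam >= L) {
    stop("lag must satisfy 0 < lambda < L (lambda = ", lam, ", L = ", L, ")")
  }
  d <- series[seq_len(L - lam)] - series[seq.int(lam + 1L, L)]
  mean(d * d)
}

#' Mean of a shift series
#'
#' Fills the lag-0 slot of the encoding: theta(0) is identically zero by
#' construction, so the slot carries the series mean instead, preserving the
#' absolute chemical-shift level that the lagged differences discard.
#'
#' @param series numeric shift series, length >= 1.
#' @return the arithmetic mean.
#' @export
acs_series_mean <- function(series) {
  if (length(series) == 0L) stop("empty series has no mean")
  mean(series)
}

#' Encode a protein as an acACS feature vector
#'
#' For each selected atom kind, in the fixed order N15, C13A, H1A, H1N, the
#' residue string is replaced by its per-atom ACS series ([acs_series()])
#' and summarized as the block
#' \code{[mean, theta(1), ..., theta(lambda)]} — lambda + 1 components per
#' atom, [acs_theta()] supplying the lagged terms. Blocks are concatenated
#' atom by atom, matching the per-atom output convention.
#'
#' @inheritParams acs_series
#' @param atoms ordered subset of [acs_atoms()]; reordered to the fixed
#'   atom order.
#' @param lambda maximum lag; must satisfy \code{0 < lambda < L}.
#' @return named numeric vector of length \code{length(atoms) * (lambda+1)};
#'   names follow \code{acACS_<atom>_lag<k>} with lag 0 the mean slot.
#' @export
encode_acacs <- function(sequence, ss, table, atoms = acs_atoms(),
                         lambda = 12L,
                         missing_policy = c("cell_row_mean", "error", "zero"),
                         nonstandard = c("error", "average"),
                         protein_id = "protein") {
  missing_policy <- match.arg(missing_policy)
  nonstandard <- match.arg(nonstandard)
  if (length(atoms) == 0L) stop("at least one atom must be selected")
  .check_atom(atoms)
  atoms <- acs_atoms()[acs_atoms() %in% atoms]
  L <- nchar(sequence)
  if (lambda <= 0L || lambda >= L) {
    stop("lambda = ", lambda, " is not in (0, L) for protein '",
         protein_id, "' of length ", L)
  }
  out <- numeric(0)
  for (atom in atoms) {
    s <- acs_series(sequence, ss, table, atom,
                    missing_policy = missing_policy,
                    nonstandard = nonstandard, protein_id = protein_id)
    block <- c(acs_series_mean(s),
               vapply(seq_len(lambda), function(l) acs_theta(s, l),
                      numeric(1)))
    names(block) <- paste0("acACS_", atom, "_lag", 0:lambda)
    out <- c(out, block)
  }
  out
}

#' Amino-acid composition
#'
#' Fraction of each of the 20 standard residues, in alphabetical order.
#'
#' @param sequence non-empty amino-acid sequence over the standard alphabet.
#' @return named numeric vector of length 20 summing to 1, names
#'   \code{AAC_<residue>}.
#' @export
aac <- function(sequence) {
  if (nchar(sequence) < 1L) stop("sequence must be non-empty")
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  odd <- which(!(res %in% acs_residues()))
  if (length(odd)) {
    stop("non-standard residue(s) at position(s) ",
         paste(odd, collapse = ", "))
  }
  counts <- table(factor(res, levels = acs_residues()))
  out <- as.numeric(counts) / length(res)
  names(out) <- paste0("AAC_", acs_residues())
  out
}

#' Dipeptide composition
#'
#' Fraction of each of the 400 ordered residue pairs over the L - 1 adjacent
#' pairs of the sequence.
#'
#' @param sequence amino-acid sequence of length >= 2 over the standard
#'   alphabet.
#' @return named numeric vector of length 400 summing to 1, names
#'   \code{DC_<pair>}.
#' @export
dc <- function(sequence) {
  L <- nchar(sequence)
  if (L < 2L) stop("dipeptide composition needs length >= 2")
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  odd <- which(!(res %in% acs_residues()))
  if (length(odd)) {
    stop("non-standard residue(s) at position(s) ",
         paste(odd, collapse = ", "))
  }
  pairs <- paste0(res[-L], res[-1L])
  lvls <- as.vector(outer(acs_residues(), acs_residues(),
                          function(a, b) paste0(a, b)))
  lvls <- sort(lvls)
  counts <- table(factor(pairs, levels = lvls))
  out <- as.numeric(counts) / (L - 1L)
  names(out) <- paste0("DC_", lvls)
  out
}

#' Fuse feature blocks into one vector
#'
#' Concatenates named feature blocks in the declared order and records the
#' block layout (kind, offset, length) so slices can be recovered from the
#' fused vector or a CSV header.
#'
#' @param ... named feature blocks (named numeric vectors), e.g.
#'   \code{fuse(acacs = v1, aac = v2)}. Block kinds must be unique.
#' @return named numeric vector with a \code{"layout"} attribute (data frame
#'   of block, offset, length).
#' @export
fuse <- function(...) {
  blocks <- list(...)
  if (length(blocks) == 0L) stop("no blocks to fuse")
  kinds <- names(blocks)
  if (is.null(kinds) || any(!nzchar(kinds))) stop("blocks must be named")
  if (anyDuplicated(kinds)) {
    stop("duplicate block kind: ", kinds[duplicated(kinds)][1L])
  }
  lens <- lengths(blocks)
  out <- unlist(blocks, use.names = TRUE)
  names(out) <- unlist(lapply(blocks, names))
  attr(out, "layout") <- data.frame(
    block = kinds,
    offset = cumsum(c(0L, lens[-length(lens)])) + 1L,
    length = as.integer(lens),
    stringsAsFactors = FALSE)
  out
}

#' Encode many proteins into a feature matrix
#'
#' Row-binds per-protein fused feature vectors for a chosen block set. The
#' acACS block uses the ACS table; AAC and DC are sequence-only.
#'
#' @param samples protein-sample data frame.
#' @param table an \code{acs_table} (required when \code{"acacs"} is among
#'   the blocks).
#' @param blocks subset of \code{c("acacs", "aac", "dc")}, in emission
#'   order.
#' @inheritParams encode_acacs
#' @return numeric matrix, one row per protein (rownames = protein_id),
#'   columns named per component.
#' @export
encode_features <- function(samples, table = NULL,
                            blocks = c("acacs", "aac", "dc"),
                            atoms = acs_atoms(), lambda = 12L,
                            missing_policy = "cell_row_mean",
                            nonstandard = "error") {
  blocks <- match.arg(blocks, several.ok = TRUE)
  if ("acacs" %in% blocks && !inherits(table, "acs_table")) {
    stop("an acs_table is required to compute the acACS block")
  }
  .validate_samples(samples)
  one <- function(r) {
    parts <- list()
    if ("acacs" %in% blocks) {
      parts$acacs <- encode_acacs(samples$sequence[r], samples$ss[r], table,
                                  atoms = atoms, lambda = lambda,
                                  missing_policy = missing_policy,
                                  nonstandard = nonstandard,
                                  protein_id = samples$protein_id[r])
    }
    if ("aac" %in% blocks) parts$aac <- aac(samples$sequence[r])
    if ("dc" %in% blocks) parts$dc <- dc(samples$sequence[r])
    do.call(fuse, parts)
  }
  vecs <- lapply(seq_len(nrow(samples)), one)
  m <- do.call(rbind, vecs)
  rownames(m) <- samples$protein_id
  m
}

#' Encode proteins with a fitted ACS table
#'
#' \code{predict} method for \code{acs_table}: applies the acACS encoder
#' (optionally fused with AAC/DC) to new (sequence, secondary structure)
#' pairs. Equivalent to [encode_features()] with the table fixed.
#'
#' @param object an \code{acs_table}.
#' @param samples protein-sample data frame with \code{protein_id},
#'   \code{sequence}, \code{ss}.
#' @param ... passed to [encode_features()] (\code{blocks}, \code{atoms},
#'   \code{lambda}, \code{missing_policy}, \code{nonstandard}).
#' @return feature matrix, one row per protein.
#' @export
predict.acs_table <- function(object, samples, ...) {
  encode_features(samples, table = object, ...)
}

#' Write a feature matrix as CSV
#'
#' One row per protein; first column \code{protein_id}, then one named
#' column per feature component.
#'
#' @param features matrix from [encode_features()].
#' @param path file path.
#' @export
write_feature_matrix <- function(features, path) {
  df <- data.frame(protein_id = rownames(features), features,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
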