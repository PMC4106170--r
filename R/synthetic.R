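#' Reference cell means for synthetic shift corpora
#'
#' A deterministic set of plausible per-cell mean shifts: each atom kind
#' gets a literature-scale base range (alpha protons near 4 ppm, amide
#' protons near 8 ppm, alpha carbons in the 45-70 ppm band, amide nitrogens
#' in the 105-130 ppm band), spread across residues, plus a
#' secondary-structure offset of the order seen in random-coil shift
#' statistics (a few tenths of a ppm for protons, 1.5-2.5 ppm for the heavy
#' atoms; helix and strand shift alpha-carbon and nitrogen in opposite
#' directions). Proline's amide-proton cells are absent (NA): proline has no
#' backbone H_N.
#'
#' @return a 240-row data frame with columns \code{atom}, \code{residue},
#'   \code{ss}, \code{true_mean}.
#' @export
default_true_means <- function() {
  grid <- .empty_grid()
  q <- match(grid$residue, acs_residues())
  base <- c(N15 = 105, C13A = 45, H1A = 4.0, H1N = 7.8)
  step <- c(N15 = 1.3, C13A = 1.2, H1A = 0.03, H1N = 0.04)
  # helix / strand offsets per atom; coil = 0
  off_h <- c(N15 = -1.5, C13A = 2.5, H1A = -0.3, H1N = -0.15)
  off_e <- c(N15 = 1.5, C13A = -1.5, H1A = 0.35, H1N = 0.2)
  mu <- base[grid$atom] + step[grid$atom] * q +
    ifelse(grid$ss == "H", off_h[grid$atom],
           ifelse(grid$ss == "E", off_e[grid$atom], 0))
  mu[grid$atom == "H1N" & grid$residue == "P"] <- NA_real_
  grid$true_mean <- unname(mu)
  grid
}

.draw_strings <- function(n, length_range, residue_probs, ss_probs,
                          ss_model = "iid", markov_stay = 0.8) {
  len_pool <- seq.int(length_range[1L], length_range[2L])
  lens <- len_pool[sample.int(length(len_pool), n, replace = TRUE)]
  seqs <- character(n)
  sss <- character(n)
  states <- acs_ss_states()
  for (i in seq_len(n)) {
    L <- lens[i]
    seqs[i] <- paste(sample(acs_residues(), L, replace = TRUE,
                            prob = residue_probs), collapse = "")
    if (ss_model == "markov") {
      # sticky chain with stationary distribution ss_probs:
      # P = s*I + (1-s) * 1 %*% t(pi)
      k <- character(L)
      k[1L] <- sample(states, 1L, prob = ss_probs)
      for (l in seq_len(L - 1L)) {
        k[l + 1L] <- if (stats::runif(1) < markov_stay) k[l] else
          sample(states, 1L, prob = ss_probs)
      }
      sss[i] <- paste(k, collapse = "")
    } else {
      sss[i] <- paste(sample(states, L, replace = TRUE, prob = ss_probs),
                      collapse = "")
    }
  }
  list(sequence = seqs, ss = sss)
}

#' Generate a synthetic chemical-shift corpus
#'
#' Emulates a curated shift benchmark with fully known ground truth: random
#' sequences and secondary structures are drawn, and every residue emits one
#' shift per applicable backbone atom from
#' Normal(true mean of its (atom, residue, SS) cell, sigma). Proline never
#' emits an amide proton. The emission log records every drawn value with
#' its cell, so table building can be checked against the generating means,
#' and the star-format round trip can be audited row by row.
#'
#' @param n_proteins number of proteins.
#' @param length_range integer \code{c(min, max)} sequence length.
#' @param sigma_ppm within-cell standard deviation in ppm (one value for all
#'   cells); default 0.3.
#' @param true_means cell means as from [default_true_means()].
#' @param seed integer seed; the whole corpus is a deterministic function of
#'   it.
#' @param residue_probs,ss_probs sampling weights for residues and SS
#'   states (defaults uniform).
#' @param ss_model \code{"iid"} per-position states, or \code{"markov"} for
#'   a sticky chain giving realistic helix/strand run lengths.
#' @return a list: \code{samples} (protein-sample data frame),
#'   \code{observations} (the emission log: protein_id, residue_index,
#'   residue, ss, atom, shift_ppm, true_mean), and \code{star} (the corpus
#'   rendered as a star-like document, parseable by [parse_shift_file()]).
#' @export
generate_shift_corpus <- function(n_proteins, length_range = c(60L, 120L),
                                  sigma_ppm = 0.3,
                                  true_means = default_true_means(),
                                  seed = 1L,
                                  residue_probs = NULL, ss_probs = NULL,
                                  ss_model = c("iid", "markov")) {
  ss_model <- match.arg(ss_model)
  stopifnot(sigma_ppm > 0, length_range[1L] >= 1L,
            length_range[1L] <= length_range[2L])
  if (is.null(residue_probs)) residue_probs <- rep(1 / 20, 20)
  if (is.null(ss_probs)) ss_probs <- rep(1 / 3, 3)

  set.seed(seed)
  drawn <- .draw_strings(n_proteins, length_range, residue_probs, ss_probs,
                         ss_model)
  samples <- data.frame(
    protein_id = sprintf("syn%04d", seq_len(n_proteins)),
    sequence = drawn$sequence, ss = drawn$ss, stringsAsFactors = FALSE)

  # expand to one row per (position, applicable atom)
  lens <- nchar(samples$sequence)
  pid <- rep(samples$protein_id, lens)
  idx <- unlist(lapply(lens, seq_len))
  res <- unlist(strsplit(samples$sequence, "", fixed = TRUE))
  kst <- unlist(strsplit(samples$ss, "", fixed = TRUE))

  per_atom <- lapply(acs_atoms(), function(atom) {
    keep <- if (atom == "H1N") res != "P" else rep(TRUE, length(res))
    data.frame(protein_id = pid[keep], residue_index = idx[keep],
               residue = res[keep], ss = kst[keep],
               atom = rep(atom, sum(keep)), stringsAsFactors = FALSE)
  })
  log <- do.call(rbind, per_atom)
  # interleave back into per-protein, per-position, per-atom order
  log <- log[order(match(log$protein_id, samples$protein_id),
                   log$residue_index, match(log$atom, acs_atoms())), ]
  rownames(log) <- NULL

  mkey <- .cell_key(true_means$atom, true_means$residue, true_means$ss)
  mu <- true_means$true_mean[match(.cell_key(log$atom, log$residue, log$ss),
                                   mkey)]
  if (anyNA(mu)) stop("true_means has no value for an emitted cell")
  log$true_mean <- mu
  log$shift_ppm <- stats::rnorm(nrow(log), mean = mu, sd = sigma_ppm)

  star <- write_shift_file(log[, c("protein_id", "residue_index", "residue",
                                   "atom", "shift_ppm")])
  list(samples = samples, observations = log, star = star)
}

#' Class configuration for synthetic labeled datasets
#'
#' @param ss_probs probabilities over (H, E, C) for per-position secondary
#'   structure.
#' @param residue_probs probabilities over the 20 residues (default
#'   uniform).
#' @return a class-config list.
#' @export
class_config <- function(ss_probs, residue_probs = rep(1 / 20, 20)) {
  stopifnot(length(ss_probs) == 3L, length(residue_probs) == 20L,
            abs(sum(ss_probs) - 1) < 1e-9,
            abs(sum(residue_probs) - 1) < 1e-9)
  list(ss_probs = ss_probs, residue_probs = residue_probs)
}

#' Two-class preset where only secondary structure separates the classes
#'
#' Both classes share an identical (uniform) residue distribution, so
#' composition features (AAC, DC) carry no class signal in expectation; the
#' classes differ only in their helix fraction, by \code{gap}, traded
#' against coil. Structure-aware features are the only route to separating
#' them — the construction behind the ablation protocol.
#'
#' @param gap difference in helix fraction between the classes (default
#'   0.2).
#' @return a list of two class configs.
#' @export
ss_signal_classes <- function(gap = 0.2) {
  base_h <- 0.3
  list(
    class1 = class_config(c(H = base_h, E = 0.2, C = 1 - base_h - 0.2)),
    class2 = class_config(c(H = base_h + gap, E = 0.2,
                            C = 1 - base_h - gap - 0.2)))
}

#' Two-class preset with no class signal at all
#'
#' Both classes use identical residue and secondary-structure
#' distributions; any classifier should sit at chance.
#'
#' @return a list of two identical class configs.
#' @export
no_signal_classes <- function() {
  cfg <- class_config(c(H = 0.35, E = 0.2, C = 0.45))
  list(class1 = cfg, class2 = cfg)
}

#' Generate a labeled synthetic sequence dataset
#'
#' Per class, sequences are drawn from the class residue distribution and
#' secondary-structure strings from the class SS distribution, i.i.d. per
#' position (or with a sticky Markov chain). Deterministic under
#' \code{seed}.
#'
#' @param n_per_class sequences per class.
#' @param classes named list of [class_config()]s (the names become the
#'   class labels).
#' @param length_range integer \code{c(min, max)} sequence length.
#' @param seed integer seed.
#' @param ss_model \code{"iid"} or \code{"markov"}.
#' @return a list with \code{samples} (protein-sample data frame) and
#'   \code{labels} (factor, one level per class).
#' @export
generate_labeled_dataset <- function(n_per_class,
                                     classes = ss_signal_classes(),
                                     length_range = c(60L, 120L),
                                     seed = 1L,
                                     ss_model = c("iid", "markov")) {
  ss_model <- match.arg(ss_model)
  stopifnot(length(classes) >= 2L, n_per_class >= 2L)
  if (is.null(names(classes))) {
    names(classes) <- paste0("class", seq_along(classes))
  }
  set.seed(seed)
  all_samples <- list()
  labels <- character(0)
  for (cname in names(classes)) {
    cfg <- classes[[cname]]
    drawn <- .draw_strings(n_per_class, length_range, cfg$residue_probs,
                           cfg$ss_probs, ss_model)
    all_samples[[cname]] <- data.frame(
      protein_id = sprintf("%s_%03d", cname, seq_len(n_per_class)),
      sequence = drawn$sequence, ss = drawn$ss, stringsAsFactors = FALSE)
    labels <- c(labels, rep(cname, n_per_class))
  }
  list(samples = do.call(rbind, c(all_samples, list(make.row.names = FALSE))),
       labels = factor(labels, levels = names(classes)))
}
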