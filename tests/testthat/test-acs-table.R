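make_obs <- function(pid, idx, res, atom, ppm) {
  data.frame(protein_id = pid, residue_index = idx, residue = res,
             atom = atom, shift_ppm = ppm, stringsAsFactors = FALSE)
}

test_that("curation removes short and unmatched proteins with reasons", {
  set.seed(30)
  lens <- c(49L, 60L, 80L)
  samples <- data.frame(
    protein_id = c("short1", "ok1", "ok2"),
    sequence = vapply(lens, function(L) random_sample(L)$sequence,
                      character(1)),
    ss = vapply(lens, function(L)
      paste(sample(acs_ss_states(), L, replace = TRUE), collapse = ""),
      character(1)),
    stringsAsFactors = FALSE)
  obs <- make_obs(c("short1", "ok1", "ok2", "ghost"), rep(1L, 4),
                  rep("A", 4), rep("H1A", 4), c(4.1, 4.2, 4.3, 4.4))
  kept <- curate_observations(obs, samples, min_length = 50L)
  expect_equal(sort(unique(kept$protein_id)), c("ok1", "ok2"))
  cur <- attr(kept, "curation")
  expect_equal(cur$n_short, 1L)
  expect_equal(cur$n_unmatched, 1L)
  expect_equal(cur$removed$reason[cur$removed$protein_id == "short1"],
               "short")
  expect_equal(cur$removed$reason[cur$removed$protein_id == "ghost"],
               "unmatched")
})

test_that("curation recount matches generator labels on a mixed fixture", {
  set.seed(31)
  lens <- c(rep(30L, 3), rep(70L, 6))
  samples <- data.frame(
    protein_id = sprintf("p%02d", 1:9),
    sequence = vapply(lens, function(L) random_sample(L)$sequence,
                      character(1)),
    ss = vapply(lens, function(L)
      paste(sample(acs_ss_states(), L, replace = TRUE), collapse = ""),
      character(1)),
    stringsAsFactors = FALSE)
  # 10 proteins carry observations: 3 short, 6 long, 1 with no sample
  obs <- make_obs(c(samples$protein_id, "p10"), rep(1L, 10),
                  substr(c(samples$sequence, "A"), 1, 1),
                  rep("C13A", 10), rnorm(10, 58, 1))
  kept <- curate_observations(obs, samples)
  expect_equal(length(unique(kept$protein_id)), 6L)
  expect_equal(attr(kept, "curation")$n_short, 3L)
  expect_equal(attr(kept, "curation")$n_unmatched, 1L)
})

test_that("identity filter collapses redundant families", {
  samp <- function(id, s) data.frame(protein_id = id, sequence = s,
                                     ss = strrep("C", nchar(s)),
                                     stringsAsFactors = FALSE)
  two_same <- rbind(samp("a", "MKVLWAAL"), samp("b", "MKVLWAAL"))
  expect_equal(identity_filter(two_same)$protein_id, "a")

  disjoint <- rbind(samp("a", "AAAAAAAA"), samp("b", "WWWWWWWW"))
  expect_equal(identity_filter(disjoint)$protein_id, c("a", "b"))
})

test_that("identity filter agrees with a brute-force all-pairs recomputation", {
  set.seed(32)
  base <- random_sample(60)$sequence
  mutate <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    pos <- sample(length(ch), k)
    ch[pos] <- sample(acs_residues(), k, replace = TRUE)
    paste(ch, collapse = "")
  }
  family <- c(base, vapply(1:4, function(i) mutate(base, 3), character(1)))
  unrelated <- vapply(1:3, function(i) random_sample(60)$sequence,
                      character(1))
  seqs <- c(family, unrelated)
  samples <- data.frame(protein_id = sprintf("s%d", seq_along(seqs)),
                        sequence = seqs,
                        ss = strrep("C", nchar(seqs)),
                        stringsAsFactors = FALSE)
  kept <- identity_filter(samples, 0.40)
  pid_fun <- function(a, b) acacs:::.pair_identity(a, b)
  want <- oracle_identity_filter(samples, 0.40, pid_fun)
  expect_equal(match(kept$protein_id, samples$protein_id), want)
  expect_equal(nrow(kept), 4L)   # one survivor of the family + 3 unrelated
})

test_that("cell means, counts and sds follow the routed observations", {
  samples <- data.frame(protein_id = "p", sequence = "AG", ss = "HH",
                        stringsAsFactors = FALSE)
  obs <- make_obs("p", c(1L, 1L, 2L), c("A", "A", "G"),
                  c("H1N", "H1N", "H1A"), c(8.0, 8.2, 4.32))
  tab <- build_acs_table(obs, samples)
  cell <- tab[tab$atom == "H1N" & tab$residue == "A" & tab$ss == "H", ]
  expect_equal(cell$mean_ppm, 8.1)
  expect_equal(cell$count, 2L)
  expect_equal(cell$sd_ppm, sd(c(8.0, 8.2)))
  single <- tab[tab$atom == "H1A" & tab$residue == "G" & tab$ss == "H", ]
  expect_equal(single$mean_ppm, 4.32)
  expect_equal(single$count, 1L)
  expect_equal(single$sd_ppm, 0)
  expect_equal(nrow(tab), 240L)
  expect_equal(sum(missing_cells(tab)), 240L - 2L)
})

test_that("routing errors name the protein and position", {
  samples <- data.frame(protein_id = "p", sequence = "AG", ss = "HH",
                        stringsAsFactors = FALSE)
  wrong_res <- make_obs("p", 1L, "G", "H1A", 4.1)
  expect_error(build_acs_table(wrong_res, samples), "residue mismatch.*p")
  past_end <- make_obs("p", 3L, "A", "H1A", 4.1)
  expect_error(build_acs_table(past_end, samples), "outside protein")
})

test_that("table building is permutation invariant and merge consistent", {
  corpus <- generate_shift_corpus(8, c(20, 40), seed = 33)
  cols <- c("protein_id", "residue_index", "residue", "atom", "shift_ppm")
  obs <- corpus$observations[, cols]
  tab <- build_acs_table(obs, corpus$samples)

  set.seed(34)
  shuffled <- obs[sample(nrow(obs)), ]
  tab_shuf <- build_acs_table(shuffled, corpus$samples)
  expect_equal(tab_shuf$mean_ppm, tab$mean_ppm)
  expect_equal(tab_shuf$count, tab$count)

  half <- nrow(obs) %/% 2
  t1 <- build_acs_table(obs[seq_len(half), ], corpus$samples)
  t2 <- build_acs_table(obs[seq.int(half + 1, nrow(obs)), ],
                        corpus$samples)
  n12 <- t1$count + t2$count
  merged_mean <- ifelse(
    n12 == 0, NA_real_,
    (ifelse(t1$count, t1$count * t1$mean_ppm, 0) +
       ifelse(t2$count, t2$count * t2$mean_ppm, 0)) / n12)
  expect_equal(tab$count, n12)
  expect_equal(tab$mean_ppm, merged_mean, tolerance = 1e-9)
})

test_that("cell means stay inside the observed range and recover truth", {
  corpus <- generate_shift_corpus(40, c(50, 80), seed = 35, sigma_ppm = 0.3)
  cols <- c("protein_id", "residue_index", "residue", "atom", "shift_ppm")
  tab <- build_acs_table(corpus$observations[, cols], corpus$samples)
  tm <- default_true_means()
  filled <- tab$count > 0
  err <- abs(tab$mean_ppm - tm$true_mean)[filled]
  bound <- (4 * 0.3 / sqrt(tab$count))[filled]
  expect_true(all(err < bound))
  # a larger corpus shrinks the worst-case error
  corpus2 <- generate_shift_corpus(160, c(50, 80), seed = 35,
                                   sigma_ppm = 0.3)
  tab2 <- build_acs_table(corpus2$observations[, cols], corpus2$samples)
  expect_lt(max(abs(tab2$mean_ppm - tm$true_mean), na.rm = TRUE),
            max(err))
})

test_that("TSV serialization round-trips the full grid losslessly", {
  corpus <- generate_shift_corpus(6, c(30, 50), seed = 36)
  cols <- c("protein_id", "residue_index", "residue", "atom", "shift_ppm")
  tab <- build_acs_table(corpus$observations[, cols], corpus$samples)
  path <- tempfile(fileext = ".tsv")
  write_acs_table(tab, path)
  expect_equal(length(readLines(path)), 241L)  # header + 240 cells
  back <- read_acs_table(path)
  expect_identical(back$mean_ppm, tab$mean_ppm)
  expect_identical(back$count, tab$count)
  expect_identical(back$sd_ppm, tab$sd_ppm)
})

test_that("reading tolerates missing rows and rejects duplicates", {
  tab <- fixture_acs_table()
  path <- tempfile(fileext = ".tsv")
  write_acs_table(tab, path)
  lines <- readLines(path)
  drop <- grep("^H1N\tP\tH\t", lines)
  expect_length(drop, 1L)
  writeLines(lines[-drop], path)
  back <- read_acs_table(path)
  miss <- back[back$atom == "H1N" & back$residue == "P" & back$ss == "H", ]
  expect_equal(miss$count, 0L)
  expect_true(is.na(miss$mean_ppm))

  writeLines(c(lines, lines[2]), path)
  expect_error(read_acs_table(path), "duplicate cell key")
})
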