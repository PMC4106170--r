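# Deterministic fixtures shared across test files.

# A fully populated ACS table with known cell values (proline's amide-proton
# cells stay structurally missing), built directly from the reference means
# so encoder tests have exact expected lookups.
fixture_acs_table <- function() {
  tm <- default_true_means()
  structure(
    data.frame(atom = tm$atom, residue = tm$residue, ss = tm$ss,
               mean_ppm = tm$true_mean,
               count = ifelse(is.na(tm$true_mean), 0L, 100L),
               sd_ppm = ifelse(is.na(tm$true_mean), NA_real_, 0.3),
               stringsAsFactors = FALSE),
    provenance = "test fixture",
    class = c("acs_table", "data.frame"))
}

# random sequence / SS pair; proline can be excluded so that all four atoms
# resolve without hitting the missing amide-proton cell
random_sample <- function(L, include_proline = TRUE) {
  pool <- acs_residues()
  if (!include_proline) pool <- setdiff(pool, "P")
  list(sequence = paste(sample(pool, L, replace = TRUE), collapse = ""),
       ss = paste(sample(acs_ss_states(), L, replace = TRUE), collapse = ""))
}

# a tiny hand-written star document: one protein, one loop
tiny_star <- function() {
  paste(c(
    "data_test",
    "",
    "save_prot1",
    "loop_",
    "  _Atom_chem_shift.Seq_ID",
    "  _Atom_chem_shift.Comp_ID",
    "  _Atom_chem_shift.Atom_ID",
    "  _Atom_chem_shift.Val",
    "  1 ALA HA 4.32",
    "stop_",
    "save_"
  ), collapse = "\n")
}
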