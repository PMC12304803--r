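# Shared fixtures, built once per test session. All geometry is
# deterministic (no RNG), so the frozen reference assignments below are
# stable across runs.

.fx <- new.env()

fixture <- function(name) {
  if (is.null(.fx[[name]])) {
    .fx[[name]] <- switch(name,
      helix20 = build_ideal_helix(20),
      helix30 = build_ideal_helix(30),
      hairpin8 = build_antiparallel_hairpin(8),
      coil20 = build_coil(20),
      proteome = simulate_proteome(synthetic_spec(seed = 11, n_proteins = 6,
                                                  n_links = 0)),
      stop("unknown fixture ", name))
  }
  .fx[[name]]
}

# Reference three-state assignments from an independent implementation of
# the DSSP hydrogen-bond-pattern algorithm (mdtraj compute_dssp,
# simplified alphabet), computed on these exact deterministic fixtures.
dssp_reference <- list(
  helix20 = strsplit("CHHHHHHHHHHHHHHHHHHC", "")[[1]],
  helix30 = strsplit(paste0("C", strrep("H", 28), "C"), "")[[1]],
  hairpin8 = strsplit("CEEEEEECCCCCEEEEEEC", "")[[1]],
  coil20 = rep("C", 20)
)

# A small annotated-record table used by atlas tests.
make_annotated <- function(categories, spacings, min_plddt = 90,
                           dataset_id = "d1") {
  n <- length(categories)
  data.frame(dataset_id = dataset_id, accession = "P00001",
             pos_a = seq_len(n), pos_b = seq_len(n) + spacings,
             linked_aa_a = "K", linked_aa_b = "K",
             spacing = spacings, category = categories,
             min_plddt = rep_len(min_plddt, n),
             continuous = categories != "mixed",
             score = 100, linker_name = "DSS", source = "synthetic",
             stringsAsFactors = FALSE)
}
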