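# Shared in-code fixtures.

records_from <- function(cdr3s, chain = "beta", ...) {
  do.call(rbind, lapply(cdr3s, function(s) make_record(s, chain, ...)))
}

# A random toy-complex spec with 0-3 planned contacts of mixed types.
random_toy_spec <- function(seed) {
  set.seed(seed)
  cdr3_len <- sample(6:9, 1)
  pep_len <- sample(4:7, 1)
  n_contacts <- sample(0:3, 1)
  plan <- if (n_contacts == 0)
    data.frame(cdr3_pos = integer(), pep_pos = integer(),
               distance = numeric(), type = character(),
               stringsAsFactors = FALSE)
  else {
    types <- sample(c("IONIC", "HBOND", "VDW"), n_contacts, replace = TRUE)
    data.frame(
      cdr3_pos = sample(seq_len(cdr3_len), n_contacts),
      pep_pos = sample(seq_len(pep_len), n_contacts, replace = TRUE),
      distance = vapply(types, function(ty)
        switch(ty, IONIC = runif(1, 2.8, 3.6), HBOND = runif(1, 2.8, 3.3),
               VDW = runif(1, 4.0, 4.8)), 0),
      type = types, stringsAsFactors = FALSE)
  }
  list(peptide_length = pep_len, cdr3_length = cdr3_len,
       contact_plan = plan, seed = seed)
}

# Minimal hand-built residue: backbone plus CB at given CA position.
stub_residue <- function(chain, subpos, resid3, ca, with_cb = TRUE) {
  atoms <- data.frame(
    chain = chain, subpos = subpos, resno = subpos, resid = resid3,
    atom = c("N", "CA", "C", "O"),
    x = ca[1] + c(-1.4, 0, 1.4, 1.6), y = ca[2] + c(0, 0, 0, 0),
    z = ca[3] + c(0.5, 0, 0.5, 1.7), stringsAsFactors = FALSE)
  if (with_cb)
    atoms <- rbind(atoms, data.frame(
      chain = chain, subpos = subpos, resno = subpos, resid = resid3,
      atom = "CB", x = ca[1], y = ca[2] - 1.2, z = ca[3] - 0.9,
      stringsAsFactors = FALSE))
  atoms
}

# Paired-chain random repertoire spec used by the oracle-equivalence tests;
# candidate count kept at or below 20.
random_repertoire_spec <- function(seed) {
  set.seed(seed * 7919)
  list(n_clusters = 1,
       members_per_cluster = sample(3:8, 1),
       cdr3_length = sample(6:9, 1),
       alphabet = c("A", "C", "D", "E"),
       decoys = c(wrong_v = 1, wrong_j = 1, wrong_length = 1,
                  wrong_epitope = 1, too_distant = 1,
                  disconnected = sample(0:1, 1)),
       seed = seed)
}
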