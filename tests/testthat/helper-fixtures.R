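# Shared fixtures, all generated in code. The bundle is built once per run.

tiny_helix <- function(n = 8, seqn = NULL) {
  if (is.null(seqn)) seqn <- paste(rep(c("L", "K", "A", "I", "E", "V",
                                         "S", "F"), length.out = n),
                                   collapse = "")
  make_ideal_helix(n, seqn)
}

# 20-mer helix with author position 10 absent entirely (chain break)
gapped_helix <- function() {
  h <- make_ideal_helix(20, strrep("A", 20))
  h$atoms <- h$atoms[h$atoms$resno != 10L, , drop = FALSE]
  validate_structure(new_structure(h$atoms, source_id = "gapped-helix"))
}

# helix where residue 5 lost its CA -> flagged unresolved
flagged_helix <- function() {
  h <- make_ideal_helix(12, strrep("A", 12))
  h$atoms <- h$atoms[!(h$atoms$resno == 5L & h$atoms$atom == "CA"), ,
                     drop = FALSE]
  validate_structure(new_structure(h$atoms, source_id = "flagged-helix"))
}

the_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_two_helix_bundle(synth_structure_spec())
    cache
  }
})

# stub scorer whose total is derived from which author position was deleted
# (the vacated residue number), so injected dG distributions are exact
deleted_position_stub <- function(total_positions) {
  scorer_spec("stub", params = list(fn = function(s, seed) {
    gone <- setdiff(seq_len(total_positions), unique(s$atoms$resno))
    if (length(gone)) as.numeric(gone[1]) else 0
  }))
}

# stub scorer returning a fixed queue of values in call order
queue_stub <- function(values) {
  env <- new.env()
  env$i <- 0L
  scorer_spec("stub", params = list(fn = function(s, seed) {
    env$i <- env$i + 1L
    values[[(env$i - 1L) %% length(values) + 1L]]
  }))
}

fast_cfg <- function(...) {
  protocol_config(n_models = 3L, n_traj = 1L, master_seed = 42L, ...)
}

records_from_truth <- function(truth) {
  lapply(seq_len(nrow(truth)), function(i) {
    v <- parse_variant(truth$variant[i])
    structure(list(variant = v, ddg_kcal = truth$ddg_kcal[i],
                   raw_stat = NA_real_, raw_scores_wt = numeric(0),
                   raw_scores_var = numeric(0), baseline = NA_real_,
                   scorer = list(backend = "synthetic",
                                 version_tag = "truth"),
                   config = NULL),
              class = "ddg_record")
  })
}
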