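# Phantom fixtures and engine runs are expensive; build them once per test
# session and share across files.
fixture_env <- new.env(parent = emptyenv())

get_fixture <- function(key) {
  if (!exists(key, envir = fixture_env)) {
    val <- switch(
      key,
      ont_h = load_ontology("human"),
      ont_m = load_ontology("macaque"),
      ph_h = generate_phantom(phantom_spec("human")),
      ph_m = generate_phantom(phantom_spec("macaque")),
      ph_h_merged = generate_phantom(phantom_spec("human", lorb_instances = 1L)),
      ph_h_left = generate_phantom(phantom_spec("human", side = "left")),
      ph_h_nocalc = generate_phantom(phantom_spec("human", calc_bank_width = 0L)),
      ph_m_left = generate_phantom(phantom_spec("macaque", side = "left")),
      lm_h = assign_labels(get_fixture("ont_h"), get_fixture("ph_h")$hemisphere),
      lm_m = assign_labels(get_fixture("ont_m"), get_fixture("ph_m")$hemisphere),
      lm_h_merged = assign_labels(get_fixture("ont_h"),
                                  get_fixture("ph_h_merged")$hemisphere),
      lm_h_left = assign_labels(get_fixture("ont_h"),
                                get_fixture("ph_h_left")$hemisphere),
      lm_h_nocalc = assign_labels(get_fixture("ont_h"),
                                  get_fixture("ph_h_nocalc")$hemisphere),
      lm_m_left = assign_labels(get_fixture("ont_m"),
                                get_fixture("ph_m_left")$hemisphere),
      stop("unknown fixture ", key)
    )
    assign(key, val, envir = fixture_env)
  }
  get(key, envir = fixture_env)
}

# Fraction of ribbon voxels farther than one voxel from any ground-truth
# border on which an engine label map agrees with the truth.
interior_agreement <- function(labelmap, phantom) {
  tl <- phantom$truth$labels
  el <- labelmap$labels
  rib <- phantom$hemisphere$ribbon > 0L
  dm <- dim(tl)
  offs <- c(1L, dm[1], dm[1] * dm[2])
  border <- array(FALSE, dm)
  idx <- which(rib)
  for (ax in 1:3) for (s in c(-1L, 1L)) {
    nb <- idx + offs[ax] * s
    ok <- nb >= 1L & nb <= prod(dm)
    hit <- idx[ok][tl[nb[ok]] > 0L & tl[nb[ok]] != tl[idx[ok]]]
    border[hit] <- TRUE
  }
  near <- border
  idxb <- which(border)
  for (ax in 1:3) for (s in c(-1L, 1L)) {
    nb <- idxb + offs[ax] * s
    nb <- nb[nb >= 1L & nb <= prod(dm)]
    near[nb] <- TRUE
  }
  interior <- rib & !near
  list(fraction = mean(el[interior] == tl[interior]),
       n_interior = sum(interior),
       n_disagree = sum(el[interior] != tl[interior]))
}
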