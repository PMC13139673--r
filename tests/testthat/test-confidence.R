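ref_af2_ortho <- p2x7_reference_plddt("AF2", "orthosteric")
ref_af2_allo <- p2x7_reference_plddt("AF2", "allosteric")
ref_af3_ortho <- p2x7_reference_plddt("AF3", "orthosteric")
ref_af3_allo <- p2x7_reference_plddt("AF3", "allosteric")

# poly-alanine trimer with the given per-residue values planted
planted_trimer <- function(ref, n_residues = 320, seed = 3, atom_sd = 0) {
  make_trimer(n_residues = n_residues,
              profile = conf_profile(base = 70,
                                     sitewise = stats::setNames(ref$plddt,
                                                                ref$resno),
                                     atom_sd = atom_sd),
              seed = seed)
}

ala_site <- function(ref, offsets = integer(0), name = "site") {
  site_definition(name, ref$resno, rep("A", nrow(ref)),
                  neighbor_offsets = offsets)
}

test_that("residue confidence averages atoms and honours ca_only", {
  f <- write_pdb_fixture(c(
    pdb_line(1, elety = "CA", b = 80),
    pdb_line(2, elety = "CB", b = 90)))
  m <- read_structure(f)
  expect_equal(residue_confidence(m, "atom_mean")$conf, 85)
  expect_equal(residue_confidence(m, "ca_only")$conf, 80)
  # AF2-style constancy: both conventions agree
  tri <- make_trimer(n_residues = 15,
                     profile = conf_profile(constant = 77.73))$model
  expect_equal(residue_confidence(tri, "atom_mean")$conf,
               residue_confidence(tri, "ca_only")$conf)
  expect_true(all(residue_confidence(tri)$conf == 77.73))
})

test_that("per-atom planted noise reproduces the generator's recorded means", {
  tri <- make_trimer(n_residues = 40,
                     profile = conf_profile(base = 77, atom_sd = 5),
                     seed = 7)
  cm <- residue_confidence(tri$model)
  key_cm <- paste(cm$chain, cm$resno)
  key_tr <- paste(tri$truth$residue_mean$chain, tri$truth$residue_mean$resno)
  expect_equal(cm$conf[match(key_tr, key_cm)],
               tri$truth$residue_mean$mean_b, tolerance = 1e-9)
})

test_that("confidence operations refuse experimental models", {
  f <- write_pdb_fixture(pdb_line(b = 25))
  m <- read_structure(f, predicted = FALSE)
  expect_error(residue_confidence(m), "experimental")
})

test_that("planted site profile reproduces the published global average", {
  tri <- planted_trimer(ref_af2_ortho)
  rep <- site_confidence(residue_confidence(tri$model), tri$model,
                         ala_site(ref_af2_ortho))
  expect_equal(round(rep$global_average, 2), 89.23)
  expect_equal(rep$per_residue$conf, ref_af2_ortho$plddt, tolerance = 1e-9)
  # global average is the arithmetic mean of the per-residue values
  expect_equal(rep$global_average, mean(rep$per_residue$conf))
})

test_that("a uniform confidence field yields that constant everywhere", {
  tri <- make_trimer(n_residues = 40, profile = conf_profile(constant = 50))
  site <- site_definition("toy", c(10, 20, 30), rep("A", 3))
  rep <- site_confidence(residue_confidence(tri$model), tri$model, site)
  expect_true(all(rep$per_residue$conf == 50))
  expect_equal(rep$global_average, 50)
})

test_that("windowed means match the generator's independent computation", {
  offsets <- c(-3L, -2L, -1L, 1L, 2L)
  for (seed in c(3, 11, 29)) {
    tri <- make_trimer(n_residues = 60,
                       profile = conf_profile(base = 70, atom_sd = 4),
                       seed = seed)
    keys <- c(5L, 22L, 40L, 58L)   # includes near-terminus clipping
    site <- site_definition("toy", keys, rep("A", 4), offsets)
    rep <- site_confidence(residue_confidence(tri$model), tri$model, site)
    gt <- truth_site_means(tri$truth, keys, offsets)
    expect_equal(rep$per_residue$conf, unname(gt$per_residue),
                 tolerance = 1e-9)
    expect_equal(rep$global_average, gt$global_average, tolerance = 1e-9)
  }
})

test_that("empty neighbour window returns the raw per-residue values", {
  tri <- make_trimer(n_residues = 40,
                     profile = conf_profile(base = 70, atom_sd = 3),
                     seed = 5)
  cm <- residue_confidence(tri$model)
  site <- site_definition("toy", c(12, 25), c("A", "A"),
                          neighbor_offsets = integer(0))
  rep <- site_confidence(cm, tri$model, site, chain_policy = "A")
  raw <- cm$conf[cm$chain == "A" & cm$resno %in% c(12, 25)]
  expect_equal(rep$per_residue$conf, raw, tolerance = 1e-12)
})

test_that("chain averaging over identical chains equals the single-chain value", {
  tri <- make_trimer(n_chains = 3, n_residues = 40,
                     profile = conf_profile(base = 70,
                                            sitewise = c(`15` = 91.5)))
  cm <- residue_confidence(tri$model)
  site <- site_definition("toy", 15, "A")
  all_ch <- site_confidence(cm, tri$model, site, "average_all")
  one_ch <- site_confidence(cm, tri$model, site, "B")
  expect_identical(all_ch$per_residue$conf, one_ch$per_residue$conf)
  expect_equal(all_ch$n_chains_used, 3)
})

test_that("site aggregation is invariant to chain and atom order", {
  tri <- make_trimer(n_residues = 30,
                     profile = conf_profile(base = 70, atom_sd = 3),
                     seed = 13)
  m <- tri$model
  set.seed(1)
  shuffled <- m
  shuffled$atoms <- m$atoms[sample(nrow(m$atoms)), , drop = FALSE]
  shuffled <- structure_model(shuffled$atoms, id = m$id)
  site <- site_definition("toy", c(10, 20), c("A", "A"))
  r1 <- site_confidence(residue_confidence(m), m, site)
  r2 <- site_confidence(residue_confidence(shuffled), shuffled, site)
  expect_equal(r1$per_residue$conf, r2$per_residue$conf, tolerance = 1e-12)
})

test_that("reported means always lie within their contributing values", {
  for (seed in 1:10) {
    tri <- make_trimer(n_residues = 30,
                       profile = conf_profile(base = runif(1, 50, 90),
                                              atom_sd = runif(1, 0, 5)),
                       seed = seed)
    cm <- residue_confidence(tri$model)
    site <- site_definition("toy", c(4, 15, 28), rep("A", 3))
    rep <- site_confidence(cm, tri$model, site)
    expect_true(all(rep$per_residue$conf >= min(cm$conf) - 1e-12))
    expect_true(all(rep$per_residue$conf <= max(cm$conf) + 1e-12))
  }
})

test_that("expected-residue mismatches and absent sites raise errors", {
  tri <- make_trimer(n_residues = 30)
  cm <- residue_confidence(tri$model)
  expect_error(
    site_confidence(cm, tri$model,
                    site_definition("bad", 10, "K")),
    "expected K")
  expect_error(
    site_confidence(cm, tri$model,
                    site_definition("gone", c(500, 600), c("A", "A"))),
    "no key residue")
  # missing residues are listed, not fatal, when at least one resolves
  rep <- site_confidence(cm, tri$model,
                         site_definition("part", c(10, 500), c("A", "A")))
  expect_equal(rep$missing, "A500")
})

test_that("global mean aggregation reproduces the published site averages", {
  expect_equal(aggregate_global_mean(ref_af2_allo$plddt), 87.30)
  expect_equal(aggregate_global_mean(ref_af3_ortho$plddt), 85.79)
  expect_equal(aggregate_global_mean(42.5), 42.5)
  expect_error(aggregate_global_mean(numeric(0)), "empty")
})

test_that("ranking reproduces the published extreme residues", {
  rk <- rank_site_residues(data.frame(label = paste0(ref_af2_ortho$aa,
                                                     ref_af2_ortho$resno),
                                      resno = ref_af2_ortho$resno,
                                      conf = ref_af2_ortho$plddt))
  expect_equal(rk$label[1], "K311")
  expect_equal(rk$conf[1], 93.78)
  expect_equal(rk$label[nrow(rk)], "N292")
  expect_equal(rk$conf[nrow(rk)], 80.30)
  rk3 <- rank_site_residues(data.frame(label = paste0(ref_af3_allo$aa,
                                                      ref_af3_allo$resno),
                                       resno = ref_af3_allo$resno,
                                       conf = ref_af3_allo$plddt))
  expect_equal(rk3$label[nrow(rk3)], "F95")
  expect_equal(rk3$conf[nrow(rk3)], 74.12)
  # all-equal values fall back to residue-number order
  tie <- rank_site_residues(data.frame(label = c("C9", "A3", "B5"),
                                       resno = c(9, 3, 5),
                                       conf = c(1, 1, 1)))
  expect_equal(tie$resno, c(3, 5, 9))
})

test_that("site reports serialize as TSV and JSON", {
  tri <- planted_trimer(ref_af2_ortho)
  rep <- site_confidence(residue_confidence(tri$model), tri$model,
                         ala_site(ref_af2_ortho))
  tsv <- tempfile(fileext = ".tsv")
  write_site_report(rep, tsv)
  tab <- read.delim(tsv)
  expect_equal(tab$pLDDT.mean[nrow(tab)], 89.23)
  js <- tempfile(fileext = ".json")
  write_site_report(rep, js, "json")
  parsed <- jsonlite::read_json(js)
  expect_equal(parsed$global_average, 89.23)
})
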