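test_that("genotype and phenotype tables round-trip through their file formats", {
  cfg <- sim_config(n = 12, p = 6, seed = 5, H2 = 0.1)
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(g, cfg)
  fg <- tempfile(fileext = ".csv")
  fp <- tempfile(fileext = ".csv")
  write_genotypes(g, fg)
  write_phenotypes(ph, fp)
  g2 <- read_genotypes(fg)
  ph2 <- read_phenotypes(fp)
  expect_equal(g2$info$marker_id, g$info$marker_id)
  expect_equal(g2$info$segregation, g$info$segregation)
  expect_equal(unname(g2$codes), unname(g$codes))
  expect_equal(unname(ph2$height), unname(ph$height), tolerance = 1e-12)
  expect_equal(ph2$times, ph$times)
  # effect curves round-trip
  # tiny n: sparse genotype classes are dropped with a warning
  scan <- suppressWarnings(lrt_scan(ph, g, mapping_control(subtests = FALSE)))
  ec <- effect_curves(scan)
  fe <- tempfile(fileext = ".csv")
  write_effect_curves(ec, fe)
  ec2 <- read_effect_curves(fe)
  expect_equal(unname(ec2$g1), unname(ec$g1), tolerance = 1e-10)
  expect_equal(ec2$ids, ec$ids)
})

test_that("malformed inputs are rejected with informative errors", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("marker_id,segregation,ind1,ind2",
               "m1,backcross,0,1"), f)
  expect_error(read_genotypes(f), "testcross, intercross")
  writeLines(c("marker_id,segregation,ind1,ind2",
               "m1,testcross,0,2"), f)
  expect_error(read_genotypes(f), "out of range")
  # unbalanced phenotype design
  writeLines(c("individual,trait,time,value",
               "a,height,1,1", "a,height,2,2",
               "a,diameter,1,1", "a,diameter,2,1.2",
               "b,height,1,1", "b,diameter,1,1"), f)
  expect_error(read_phenotypes(f), "unbalanced")
  writeLines(c("individual,trait,time,value", "a,girth,1,1"), f)
  expect_error(read_phenotypes(f), "height, diameter")
})

test_that("pipeline configuration round-trips and rejects unknown keys", {
  fy <- tempfile(fileext = ".yaml")
  write_config(list(seed = 9, sim = list(n = 20, H2 = 0.1)), fy)
  cfg <- read_config(fy)
  expect_equal(cfg$seed, 9)
  expect_equal(cfg$sim$n, 20)
  expect_equal(cfg$sim$H2, 0.1)
  # defaults fill the gaps and survive a second round-trip
  fy2 <- tempfile(fileext = ".json")
  write_config(cfg, fy2)
  cfg2 <- read_config(fy2)
  expect_equal(cfg2$sim, cfg$sim)
  write_config(list(simulate = list(n = 5)), fy)
  expect_error(read_config(fy), "simulate")
  write_config(list(sim = list(individuals = 5)), fy)
  expect_error(read_config(fy), "individuals")
})

test_that("the manifest lists every emitted file once", {
  fm <- tempfile(fileext = ".json")
  man <- write_manifest(fm, list(seed = 1), c(a = "x.csv", b = "y.tsv"),
                        warnings = "one warning")
  back <- jsonlite::read_json(fm)
  expect_equal(unlist(back$outputs, use.names = FALSE), c("x.csv", "y.tsv"))
  expect_equal(length(back$outputs), 2)
  expect_equal(back$package, "crinet")
})

test_that("the command-line pipeline runs end to end on a small dataset", {
  skip_if_not_installed("optparse")
  cli <- system.file("cli", "crinet.R", package = "crinet")
  expect_true(nzchar(cli))
  out <- file.path(tempdir(), "cli_run")
  cfgf <- tempfile(fileext = ".yaml")
  write_config(list(seed = 4,
                    sim = list(n = 40, p = 30, H2 = 0.3, effect_size = 0.12),
                    clustering = list(L_range = 1:3),
                    mapping = list(subtests = FALSE)), cfgf)
  res <- system2("Rscript", c(cli, "all", "--config", shQuote(cfgf),
                              "--out", shQuote(out)),
                 stdout = TRUE, stderr = TRUE)
  expect_equal(attr(res, "status"), NULL)  # exit code 0
  for (f in c("genotypes.csv", "phenotypes.csv", "mapping.tsv",
              "effect_curves.csv", "assignments.tsv", "module_curves.csv",
              "manifest.json"))
    expect_true(file.exists(file.path(out, f)), label = f)
  man <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_gte(length(man$outputs), 4)
})
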