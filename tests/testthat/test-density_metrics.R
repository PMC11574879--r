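test_that("density is count over area with derived-demarcation aggregation", {
  # 50 cells in 0.5 mm2 -> 100 cells/mm2; empty compartment -> 0
  cells <- data.table::data.table(
    sample_id = "S1", core_id = "c1", cell_id = as.character(1:50),
    x_um = 0, y_um = 0, compartment = "stroma",
    CD8_int = 10)
  areas <- data.table::data.table(
    sample_id = "S1", core_id = "c1",
    demarcation = c("tumor_nest", "stroma", "liver"),
    area_mm2 = c(0.5, 0.5, 0.5))
  calls <- apply_thresholds(cells, list(CD8 = 1))
  dm <- compute_densities(calls, cells, areas)
  get <- function(d) dm$density[dm$phenotype == "CD8" & dm$demarcation == d]
  expect_equal(get("stroma"), 100)
  expect_equal(get("tumor_nest"), 0)
  # tumor_area aggregates counts and areas: 50 / (0.5 + 0.5)
  expect_equal(get("tumor_area"), 50)
  expect_equal(get("total_tissue"), 50 / 1.5)
  expect_equal(get("total_excluding_liver"), get("tumor_area"))
})

test_that("densities match brute-force recounts on a synthetic cohort", {
  b <- generate_cohort(sim_config(n_per_group = 4, cells_per_core = 150,
                                  seed = 29))
  th <- fit_thresholds(b$cells)
  calls <- apply_thresholds(b$cells, th)
  dm <- compute_densities(calls, b$cells, b$areas)
  for (d in c("stroma", "tumor_area", "total_tissue")) {
    oracle <- brute_density(b$cells, calls$CD8, b$areas, d)
    got <- dm[dm$phenotype == "CD8" & dm$demarcation == d, ]
    expect_equal(got$density, as.numeric(oracle[got$sample_id]),
                 tolerance = 1e-12, info = d)
  }
  # aggregation identity on one core: (n_nest + n_stroma)/(a_nest + a_stroma)
  cores <- attr(dm, "cores")
  one <- cores[cores$phenotype == "CD8" & cores$demarcation == "tumor_area", ][1, ]
  sel <- b$cells$sample_id == one$sample_id & b$cells$core_id == one$core_id &
    b$cells$compartment %in% c("tumor_nest", "stroma")
  a <- sum(b$areas$area_mm2[b$areas$sample_id == one$sample_id &
                              b$areas$core_id == one$core_id &
                              b$areas$demarcation %in% c("tumor_nest", "stroma")])
  expect_equal(one$density, sum(calls$CD8[sel]) / a, tolerance = 1e-12)
})

test_that("tumor_area density lies between nest and stroma densities", {
  b <- generate_cohort(sim_config(n_per_group = 4, cells_per_core = 150,
                                  seed = 31))
  th <- fit_thresholds(b$cells)
  calls <- apply_thresholds(b$cells, th)
  cores <- attr(compute_densities(calls, b$cells, b$areas), "cores")
  for (ph in c("CD8", "CD68")) {
    w <- data.table::dcast(
      cores[cores$phenotype == ph &
              cores$demarcation %in% c("tumor_nest", "stroma", "tumor_area"), ],
      sample_id + core_id ~ demarcation, value.var = "density")
    expect_true(all(w$tumor_area >= pmin(w$tumor_nest, w$stroma) - 1e-9 &
                      w$tumor_area <= pmax(w$tumor_nest, w$stroma) + 1e-9),
                info = ph)
  }
})

test_that("scale equivariance: doubling areas halves densities, ratios invariant", {
  b <- generate_cohort(sim_config(n_per_group = 4, cells_per_core = 150,
                                  seed = 37))
  th <- fit_thresholds(b$cells)
  calls <- apply_thresholds(b$cells, th)
  panels <- lapply(default_panel_paths()[c("lymphoid", "myeloid")], read_panel)
  mats <- lapply(panels, function(p) assign_phenotypes(calls, p)$matrix)
  mat <- do.call(cbind, mats)
  dm1 <- compute_densities(mat, b$cells, b$areas)
  a2 <- data.table::copy(b$areas)
  a2$area_mm2 <- 2 * a2$area_mm2
  dm2 <- compute_densities(mat, b$cells, a2)
  expect_equal(dm2$density, dm1$density / 2, tolerance = 1e-12)

  r1 <- compute_ratios(dm1)
  r2 <- compute_ratios(dm2)
  expect_equal(r2$value, r1$value, tolerance = 1e-12)
})

test_that("ratios divide densities with zero denominators recorded missing", {
  dm <- data.table::data.table(
    sample_id = rep(c("S1", "S2"), each = 4),
    phenotype = rep(c("CD8_total", "M2", "CD8_total", "M2"), 2),
    demarcation = rep(c("stroma", "stroma", "tumor_nest", "tumor_nest"), 2),
    density = c(100, 50, 80, 10,      # S1: SIA_M2 = 2
                60, 0, 30, 5))        # S2: denominator 0 -> missing
  spec <- default_ratio_specs()[1, ]  # SIA_M2
  rt <- compute_ratios(dm, spec)
  expect_equal(rt$value[rt$sample_id == "S1"], 2)
  expect_true(is.na(rt$value[rt$sample_id == "S2"]))

  bad <- data.table::copy(spec); bad$den_phenotype <- "nonexistent"
  expect_error(compute_ratios(dm, bad), class = "tq_config_error")
})

test_that("ratio table equals element-wise division on a synthetic cohort", {
  b <- generate_cohort(sim_config(n_per_group = 4, cells_per_core = 200,
                                  seed = 41))
  th <- fit_thresholds(b$cells)
  calls <- apply_thresholds(b$cells, th)
  panels <- lapply(default_panel_paths()[c("lymphoid", "myeloid")], read_panel)
  mat <- do.call(cbind, lapply(panels, function(p) {
    assign_phenotypes(calls, p)$matrix
  }))
  dm <- compute_densities(mat, b$cells, b$areas)
  rt <- compute_ratios(dm)
  s <- unique(dm$sample_id)[1]
  num <- dm$density[dm$sample_id == s & dm$phenotype == "CD8_total" &
                      dm$demarcation == "stroma"]
  den <- dm$density[dm$sample_id == s & dm$phenotype == "M2" &
                      dm$demarcation == "stroma"]
  got <- rt$value[rt$sample_id == s & rt$ratio_name == "SIA_M2"]
  expect_equal(got, if (den > 0) num / den else NA_real_)
})
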