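test_that("g-ratio mapping is exact at its anchors and monotone", {
  expect_equal(wraps_to_gratio(0), 1)
  expect_equal(wraps_to_gratio(10), 0.8, tolerance = 1e-9)
  # closed form at 5 wraps with lamella = d/80
  expect_equal(wraps_to_gratio(5), 1 / (1 + 10 / 80), tolerance = 1e-12)
  g <- wraps_to_gratio(0:10)
  expect_true(all(diff(g) < 0))
  expect_error(wraps_to_gratio(-1), "non-negative")
})

test_that("myelin membrane scale is 1 at 0 wraps and strictly decreasing", {
  s <- myelin_membrane_scale(0:10)
  expect_equal(s[1], 1)
  expect_true(all(diff(s) < 0))
  expect_equal(s, 1 / (1 + 2 * (0:10)))
})

test_that("specification objects validate their invariants", {
  expect_error(morphology_spec(2), "ais_length")
  expect_error(morphology_spec(61), "ais_length")
  expect_error(morphology_spec(20, axon_diam = -1), "positive")
  expect_error(morphology_spec(20, n_internodes = 10), ">= 40")
  expect_error(morphology_spec(20, soma_length = 3), "compartment_size")
  expect_error(myelin_spec(11), "0..10")
  expect_error(myelin_spec(2.5), "0..10")
  expect_error(channel_densities(nav_soma = -1), "non-negative")
})

test_that("compartment counts match the discretization rule", {
  mo <- test_morph(20.3)
  m <- build_cell(mo, channel_densities(), myelin_spec(10))
  comp <- m$comp
  counts <- table(comp$section)
  expect_equal(unname(counts[["soma"]]), ceiling(mo$soma_length / 5))
  expect_equal(unname(counts[["dendrite"]]), ceiling(mo$dend_length / 5))
  expect_equal(unname(counts[["AIS"]]), ceiling(mo$ais_length / 1))
  expect_equal(unname(counts[["internode"]]),
               40 * ceiling(mo$internode_length / 5))
  expect_equal(unname(counts[["node"]]), 40)
  expect_equal(m$n, nrow(comp))
})

test_that("AIS sodium profile expresses the proximal/distal asymmetry", {
  m <- build_cell(test_morph(20.3), channel_densities(), myelin_spec(10))
  ais <- m$comp[m$comp$section == "AIS", ]
  # proximal isoform decreasing, distal isoform increasing along the AIS
  expect_true(all(diff(ais$gna12) < 0))
  expect_true(all(diff(ais$gna16) > 0))
  expect_gt(ais$gna12[1], ais$gna16[1])
  expect_gt(ais$gna16[nrow(ais)], ais$gna12[nrow(ais)])
})

test_that("AIS channel totals and section axial resistance survive refinement", {
  ch <- channel_densities()
  total_na <- function(step) {
    m <- build_cell(test_morph(20.3, compartment_size = step), ch,
                    myelin_spec(10))
    ais <- m$comp[m$comp$section == "AIS", ]
    sum((ais$gna12 + ais$gna16) * ais$area)
  }
  expect_equal(total_na(5), total_na(2.5), tolerance = 0.01)

  axial_total <- function(step) {
    m <- build_cell(test_morph(20.3, compartment_size = step), ch,
                    myelin_spec(10))
    sum(1 / demyelin:::cable_pars(m)$ga)
  }
  expect_equal(axial_total(5), axial_total(2.5), tolerance = 1e-3)
})

test_that("conserved AIS pool: total sodium is invariant to AIS length", {
  ch <- channel_densities()
  tot <- vapply(c(5, 20.3, 50), function(L) {
    m <- build_cell(test_morph(L), ch, myelin_spec(10))
    ais <- m$comp[m$comp$section == "AIS", ]
    sum((ais$gna12 + ais$gna16) * ais$area)
  }, numeric(1))
  expect_equal(tot[1], tot[2], tolerance = 0.01)
  expect_equal(tot[3], tot[2], tolerance = 0.01)
})

test_that("demyelination edits only the targeted internodes", {
  ch <- channel_densities()
  base <- build_cell(test_morph(20.3), ch, myelin_spec(10))
  expect_identical(apply_demyelination(base, integer(0), 0), base)

  les <- apply_demyelination(base, 1:20, 0)
  sel <- les$comp$section == "internode" & les$comp$number <= 20
  expect_true(all(les$comp$wraps[sel] == 0))
  expect_equal(les$comp$cm[sel], rep(1, sum(sel)))
  expect_identical(les$comp[!sel, ], base$comp[!sel, ])
  expect_equal(les$wraps, c(rep(0L, 20), rep(10L, 20)))

  expect_error(apply_demyelination(base, 41, 0), "out of range")
  expect_error(apply_demyelination(base, 1:5, 12), "wraps")

  # rebuilding from the same specs is bit-reproducible
  again <- build_cell(test_morph(20.3), ch, myelin_spec(10))
  expect_identical(base$comp, again$comp)
})

test_that("somatic input resistance falls when myelin is removed", {
  ch <- channel_densities()
  rin <- function(wraps) {
    m <- build_cell(test_morph(20.3), ch, myelin_spec(wraps))
    s <- cached_settled(paste0("rin", wraps), m)
    p <- stimulus_protocol(amplitude = -20, onset = 2, duration = 60,
                           t_stop = 70)
    tr <- integrate_cable(m, p, s)
    dv <- s$rest[["soma"]] - min(tr$v[, "soma"])
    dv / 20                               # GOhm
  }
  expect_gt(rin(10), rin(0))
})
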