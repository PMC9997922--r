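test_that("scramble competition splits each cell's unit equally", {
  land <- mini_land()
  cl <- land$cells
  interior <- cl$cell[cl$patch == 1 & cl$col == 4 & cl$row == 5]

  # a lone interior individual acquires its full goal (37 unshared units)
  expect_equal(allocate_resources(land, interior, goal = 2.5), 1)

  # with the goal set to the whole neighborhood yield, the equal-split rule
  # is visible: alone = 37/37, two co-located individuals = 18.5/37 each
  expect_equal(allocate_resources(land, interior, goal = 37), 1)
  fr <- allocate_resources(land, rep(interior, 2), goal = 37)
  expect_equal(fr, c(0.5, 0.5))

  # a saturated landscape (one individual per cell): interior individuals
  # acquire ~1 unit each by symmetry of the overlapping neighborhoods
  fr_all <- allocate_resources(land, cl$cell, goal = 2.5)
  inner <- cl$patch == 1 & cl$col >= 3 & cl$col <= 4 & cl$row >= 4 & cl$row <= 5
  acquired <- fr_all[which(inner)] * 2.5
  expect_equal(unname(acquired), rep(1, sum(inner)), tolerance = 0.1)
})

test_that("pair formation is exclusive and radius-limited", {
  land <- mini_land()
  cl <- land$cells
  c1 <- cl$cell[cl$patch == 1][20]
  far <- cl$cell[cl$patch == 1 & cl$col == 7 & cl$row == 9] # >3 cells away

  set.seed(1)
  # one female and one male in the same cell form one pair
  p <- form_pairs(land, tibble::tibble(id = 1:2, sex = c("F", "M"),
                                       cell = c(c1, c1)))
  expect_equal(nrow(p), 1L)
  expect_equal(p$female, 1L)
  expect_equal(p$male, 2L)

  # a female with no male within the pairing radius stays unpaired
  p2 <- form_pairs(land, tibble::tibble(id = 1:2, sex = c("F", "M"),
                                        cell = c(c1, far)))
  expect_equal(nrow(p2), 0L)

  # two females, one male in range: exactly one pair
  p3 <- form_pairs(land, tibble::tibble(id = 1:3, sex = c("F", "F", "M"),
                                        cell = c(c1, c1, c1)))
  expect_equal(nrow(p3), 1L)
  expect_equal(p3$male, 3L)

  # the nearest male wins; ties broken by smallest id
  nb <- land$nbr[c1, land$nbr[c1, ] > 0][1]
  p4 <- form_pairs(land, tibble::tibble(id = 1:3, sex = c("F", "M", "M"),
                                        cell = c(c1, nb, c1)))
  expect_equal(p4$male, 3L) # co-located male beats the adjacent one
  p5 <- form_pairs(land, tibble::tibble(id = 1:3, sex = c("F", "M", "M"),
                                        cell = c(c1, c1, c1)))
  expect_equal(p5$male, 2L) # equidistant: smallest id
})

test_that("litter sizes are truncated resource-scaled normal draws", {
  params <- demography_params()
  set.seed(2)
  x <- offspring_number(rep(1, 1e5), params)
  expect_true(all(x >= 0))
  expect_equal(mean(x), params$fecundity_max, tolerance = 0.03)
  # at zero resources the mean collapses toward zero
  x0 <- offspring_number(rep(0, 1e5), params)
  expect_lt(mean(x0), 0.2)
  expect_gt(mean(x0), 0) # the truncated normal still allows rare litters
})

test_that("dispersal respects path lengths, barriers, and habitat", {
  land <- mini_land()
  cl <- land$cells
  set.seed(4)
  starts <- rep(cl$cell[cl$patch == 1][30], 500)

  short <- disperse(land, starts, dispersal_params("short"))
  expect_true(all(short$path_length >= 1 & short$path_length <= 5))
  long <- disperse(land, starts, dispersal_params("long"))
  expect_true(all(long$path_length >= 5 & long$path_length <= 25))

  # settlement cells are always habitat cells (cell ids are in range)
  expect_true(all(short$cell >= 1 & short$cell <= land$n))

  # with all permeabilities in {0, 1} the gap-crossing flag is never set
  expect_false(any(short$crossed_gap))
  iso <- apply_epoch(land, epoch_spec("isolated"))
  d_iso <- disperse(iso, rep(cl$cell[cl$patch == 2][1], 300),
                    dispersal_params("long"))
  expect_false(any(d_iso$crossed_gap))
  # absolute barriers: every disperser settles in its natal patch
  expect_true(all(cl$patch[d_iso$cell] == 2))

  # full persistence on open ground gives straight paths
  big <- build_landscape()
  bc <- big$cells
  center <- bc$cell[bc$patch == 1 & bc$col == 13 & bc$row == 25]
  st <- disperse(big, rep(center, 200), dispersal_params("short", autocorrelation = 100))
  d <- hex_distance(bc$q[center], bc$r[center], bc$q[st$cell], bc$r[st$cell])
  expect_equal(d, st$path_length)
})

test_that("gap crossings occur only through gap edges and are flagged", {
  land <- apply_epoch(mini_land(), epoch_spec("semi_connected",
                                              gap_permeability = 0.7))
  cl <- land$cells
  gap_from <- land$interpatch$from[land$interpatch$is_gap &
                                     land$interpatch$patch_from == 1][1]
  set.seed(9)
  d <- disperse(land, rep(gap_from, 2000), dispersal_params("long"))
  moved <- cl$patch[d$cell] != 1
  expect_true(any(moved))
  # leaving the natal patch requires a flagged gap crossing
  expect_true(all(d$crossed_gap[moved]))
})

test_that("survival combines stage, resources, and adaptation", {
  params <- demography_params()
  expect_equal(survival_probability("adult", 0.5, params), 0.885)
  expect_equal(survival_probability("juvenile", 0.5, params), 0.500)
  # the resource penalty is additive mortality below 20% of the goal
  expect_equal(survival_probability("juvenile", 0.1, params), 0.40)
  expect_equal(survival_probability("adult", 0.19, params), 0.785)
  # adaptive benefit: S per matching allele copy, juveniles only
  expect_equal(survival_probability("juvenile", 0.5, params,
                                    adaptive_copies = 2, S = 0.10), 0.70)
  expect_equal(survival_probability("adult", 0.5, params,
                                    adaptive_copies = 2, S = 0.10), 0.885)
  # cap at 1 and floor at 0
  expect_equal(survival_probability("juvenile", 1, params,
                                    adaptive_copies = 10, S = 0.10), 1)
  p0 <- demography_params(s_juv = 0.05)
  expect_equal(survival_probability("juvenile", 0.1, p0), 0)

  set.seed(6)
  expect_equal(mean(apply_survival(rep(0.885, 1e5))), 0.885, tolerance = 0.01)
  expect_true(all(apply_survival(rep(1, 100))))
  expect_false(any(apply_survival(rep(0, 100))))
})
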