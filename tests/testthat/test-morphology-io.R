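test_that("SWC parsing validates structure and reports malformed input", {
  path <- writeTinySWC()
  m <- readSWC(path)
  expect_s4_class(m, "NeuronMorphology")
  expect_equal(nNodes(m), 3L)
  sec <- sectionTable(m)
  expect_equal(nrow(sec), 1L)
  expect_true(sec$is_terminal[1])

  orphan <- tempfile(fileext = ".swc")
  writeLines(c("1 1 0 0 0 10 -1", "2 4 0 50 0 1 9"), orphan)
  expect_error(readSWC(orphan), "missing parent")

  badr <- tempfile(fileext = ".swc")
  writeLines(c("1 1 0 0 0 10 -1", "2 4 0 50 0 0 1"), badr)
  expect_error(readSWC(badr), "radius")

  mal <- tempfile(fileext = ".swc")
  writeLines(c("# comment", "1 1 0 0 0 10 -1", "2 4 0 50"), mal)
  expect_error(readSWC(mal), "line 3")

  expect_error(readSWC(tempfile()), "not found")
})

test_that("SWC write/read round-trips and renumbers non-contiguous ids", {
  m <- smallTree(2)
  out <- tempfile(fileext = ".swc")
  writeSWC(m, out)
  m2 <- readSWC(out)
  nd1 <- morphNodes(m)
  nd2 <- morphNodes(m2)
  expect_equal(nrow(nd1), nrow(nd2))
  expect_equal(nd2$x, nd1$x, tolerance = 1e-5)
  expect_equal(nd2$radius, nd1$radius, tolerance = 1e-5)
  expect_equal(totalDendriticLength(m2), totalDendriticLength(m),
               tolerance = 1e-5)

  # non-contiguous ids: renumbered contiguously, mapping returned
  nd <- data.frame(id = c(10L, 20L, 35L), type = c(1L, 4L, 4L),
                   x = 0, y = c(0, 50, 100), z = 0,
                   radius = c(10, 1, 1), parent = c(-1L, 10L, 20L))
  gap <- neuronMorphology(nd)
  out2 <- tempfile(fileext = ".swc")
  mapping <- withVisible(writeSWC(gap, out2))$value
  expect_equal(unname(mapping), 1:3)
  expect_equal(names(mapping), c("10", "20", "35"))
  renum <- readSWC(out2)
  expect_equal(morphNodes(renum)$id, 1:3)

  expect_error(neuronMorphology(nd[0, ]), "no nodes")
})

test_that("dendritic length, radial and path distances follow definitions", {
  # straight chain of 3 nodes spaced 50 um -> 0.1 mm
  nd <- data.frame(id = 1:3, type = c(1L, 4L, 4L), x = 0,
                   y = c(0, 50, 100), z = 0,
                   radius = c(10, 1, 1), parent = c(-1L, 1L, 2L))
  m <- neuronMorphology(nd)
  expect_equal(totalDendriticLength(m), 0.1)
  # straight cable: path equals radial everywhere
  expect_equal(pathDistance(m, 2:3), radialDistance(m, 2:3))

  # soma-only tree -> 0 mm
  soma <- neuronMorphology(data.frame(id = 1L, type = 1L, x = 0, y = 0,
                                      z = 0, radius = 10, parent = -1L))
  expect_equal(totalDendriticLength(soma), 0)
  expect_equal(radialDistance(soma, 1L), 0)
  expect_equal(pathDistance(soma, 1L), 0)

  # bent path: two 100 um edges at a right angle
  bent <- neuronMorphology(data.frame(
    id = 1:3, type = c(1L, 4L, 4L),
    x = c(0, 0, 100), y = c(0, 100, 100), z = 0,
    radius = c(10, 1, 1), parent = c(-1L, 1L, 2L)
  ))
  expect_equal(pathDistance(bent, 3L), 200)
  expect_equal(radialDistance(bent, 3L), sqrt(2) * 100, tolerance = 1e-9)

  # node at (300, 0, 0) with soma at origin -> 300 um radial
  far <- neuronMorphology(data.frame(
    id = 1:2, type = c(1L, 4L), x = c(0, 300), y = 0, z = 0,
    radius = c(10, 1), parent = c(-1L, 1L)
  ))
  expect_equal(radialDistance(far, 2L), 300)

  # path >= radial for every node of a branched tree
  tree <- smallTree(3)
  expect_true(all(pathDistance(tree) >= radialDistance(tree) - 1e-9))

  # section lengths sum to the dendritic total
  sec <- sectionTable(tree)
  expect_equal(sum(sec$length_um[sec$type %in% c(3L, 4L)]) / 1000,
               totalDendriticLength(tree), tolerance = 1e-9)

  expect_error(radialDistance(tree, 999999L), "not in morphology")
})

test_that("lambda_100 closed form and scaling laws hold", {
  expect_equal(spaceConstant100(1, 70, 1), 337.2, tolerance = 1e-3)
  expect_equal(spaceConstant100(4, 70, 1), 2 * spaceConstant100(1, 70, 1))
  expect_equal(spaceConstant100(1, 280, 1), spaceConstant100(1, 70, 1) / 2)
  expect_error(spaceConstant100(-1, 70, 1), "positive")
})

test_that("d-lambda discretization picks the smallest odd segment count", {
  # 100 um section with lambda_100 = 337 um -> smallest odd n with
  # 100/n < 33.7 is n = 3
  m <- chainMorph(100, diam_um = 1)
  g <- compartmentalize(m, uniformProfile(ra = 70), d_lambda = 0.1)
  counts <- table(segmentTable(g)$section)
  expect_equal(unname(counts[["1"]]), 3L)

  # 10 um section is already fine -> n = 1
  m2 <- chainMorph(10, diam_um = 1)
  g2 <- compartmentalize(m2, uniformProfile(ra = 70), d_lambda = 0.1)
  expect_equal(sum(segmentTable(g2)$section == 1L), 1L)

  # halving d_lambda never decreases any section's segment count
  tree <- smallTree(3)
  n1 <- table(segmentTable(compartmentalize(tree, d_lambda = 0.1))$section)
  n2 <- table(segmentTable(compartmentalize(tree, d_lambda = 0.05))$section)
  expect_true(all(as.integer(n2) >= as.integer(n1)))

  expect_error(compartmentalize(tree, d_lambda = 0), "positive")
})

test_that("compartment grids satisfy the geometric invariants", {
  tree <- smallTree(3)
  g <- compartmentalize(tree)
  sg <- segmentTable(g)
  expect_true(all(sg$area_um2 > 0))
  expect_true(all(sg$diam_um > 0))
  expect_true(all(table(sg$section[sg$section > 0]) %% 2L == 1L))
  # segment midpoints: path >= radial
  expect_true(all(sg$path_um >= sg$radial_um - 1e-6))
  # summed segment lengths reproduce section lengths
  sec <- sectionTable(tree)
  bysec <- tapply(sg$length_um[sg$section > 0], sg$section[sg$section > 0], sum)
  expect_equal(as.numeric(bysec), sec$length_um[as.integer(names(bysec))],
               tolerance = 1e-9)
  # summed segment areas reproduce the whole-section lateral area
  # (uniform radius, so the section is a plain cylinder)
  cyl <- chainMorph(100, diam_um = 2, soma_radius = 1)
  gc <- compartmentalize(cyl, uniformProfile())
  sgc <- segmentTable(gc)
  dend <- sgc$section == 1L
  expect_equal(sum(sgc$area_um2[dend]), pi * 2 * 100, tolerance = 1e-6)

  # morphometry report covers every section
  rep <- morphometryReport(tree)
  expect_equal(nrow(rep), nrow(sec))
})
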