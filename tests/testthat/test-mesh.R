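test_that("two-needle geometry satisfies its contracts", {
  m <- fix("needle")
  expect_s3_class(m, "ep_mesh")
  expect_silent(validate_mesh(m))
  expect_true(all(m$vol > 0))
  # tagged electrode area approximates the cylinder lateral area pi * d * L
  target <- pi * 1.2e-3 * 10e-3
  for (tag in c("ELECTRODE_A", "ELECTRODE_B")) {
    expect_lt(abs(electrode_area(m, tag) - target) / target, 0.05)
  }
  expect_equal(electrode_area(m, "ELECTRODE_A"),
               electrode_area(m, "ELECTRODE_B"), tolerance = 1e-12)
  # boundary areas partition the domain surface: outer area covers the box
  # plus the insulated shaft walls, so it exceeds the bare box area
  expect_gt(electrode_area(m, "OUTER"), 6 * 0.06^2 - 4 * 0.06^2 / 6)
})

test_that("infeasible needle geometries are rejected with a description", {
  expect_error(build_two_needle_geometry(electrodeDiameter = 11e-3,
                                         centreSpacing = 10e-3),
               "overlapping")
  expect_error(build_two_needle_geometry(domainSize = 20e-3), "margin")
})

test_that("box geometry tags the two plate faces exactly", {
  m <- build_box_geometry(lengths = c(0.01, 0.02, 0.03), n = c(2, 3, 4))
  expect_equal(electrode_area(m, "ELECTRODE_A"), 0.02 * 0.03)
  expect_equal(electrode_area(m, "ELECTRODE_B"), 0.02 * 0.03)
  expect_equal(electrode_area(m, "OUTER"), 2 * 0.01 * 0.02 + 2 * 0.01 * 0.03)
  expect_equal(sum(m$vol), 0.01 * 0.02 * 0.03, tolerance = 1e-12)
})

test_that("MSH 2.2 and 4.1 files round-trip connectivity and tags", {
  m <- build_box_geometry(lengths = c(0.01, 0.008, 0.006), n = c(3, 2, 2))
  for (v in c("2.2", "4.1")) {
    f <- withr::local_tempfile(fileext = ".msh")
    write_mesh_msh(m, f, version = v)
    back <- read_mesh_msh(f)
    expect_equal(back$nodes, m$nodes, tolerance = 1e-14)
    expect_identical(dim(back$tets), dim(m$tets))
    expect_equal(sum(back$vol), sum(m$vol), tolerance = 1e-12)
    for (tag in c("ELECTRODE_A", "ELECTRODE_B", "OUTER")) {
      expect_equal(electrode_area(back, tag), electrode_area(m, tag),
                   tolerance = 1e-12)
    }
  }
})

test_that("needle mesh write-then-read preserves connectivity", {
  m <- fix("needle")
  f <- withr::local_tempfile(fileext = ".msh")
  write_mesh_msh(m, f)
  back <- read_mesh_msh(f)
  expect_identical(back$tets, m$tets)
  expect_equal(electrode_area(back, "ELECTRODE_A"),
               electrode_area(m, "ELECTRODE_A"), tolerance = 1e-12)
})

test_that("the packaged fixture mesh loads with two electrode groups", {
  f <- system.file("extdata", "fixture_box_synthetic.msh",
                   package = "porodyn", mustWork = TRUE)
  m <- read_mesh_msh(f)
  expect_equal(nrow(m$tets), 216)
  expect_gt(sum(m$triTag == "ELECTRODE_A"), 0)
  expect_gt(sum(m$triTag == "ELECTRODE_B"), 0)
  expect_silent(validate_mesh(m))
})

test_that("malformed MSH input yields distinct errors", {
  f <- withr::local_tempfile(fileext = ".msh")
  writeLines(c("$MeshFormat", "3.0 0 8", "$EndMeshFormat"), f)
  expect_error(read_mesh_msh(f), "unsupported MSH version")
  # missing electrode physical groups
  m <- build_box_geometry(n = c(2, 2, 2))
  f2 <- withr::local_tempfile(fileext = ".msh")
  write_mesh_msh(m, f2)
  txt <- gsub("electrode_a", "anode", readLines(f2))
  writeLines(txt, f2)
  expect_error(read_mesh_msh(f2), "missing physical groups")
  # degenerate element: a tet with a repeated node has zero volume
  f3 <- withr::local_tempfile(fileext = ".msh")
  write_mesh_msh(m, f3)
  txt <- readLines(f3)
  i <- grep("^[0-9]+ 4 2 4 4 ", txt)[1]
  parts <- strsplit(txt[i], " ")[[1]]
  parts[7] <- parts[6]
  txt[i] <- paste(parts, collapse = " ")
  writeLines(txt, f3)
  expect_error(read_mesh_msh(f3), "degenerate.*element index 1")
})

test_that("baseline current converges under refinement on the plate geometry", {
  tab <- mesh_convergence_study("box", targetEdgeLength = 5e-3, levels = 2)
  expect_equal(nrow(tab), 2)
  # uniform field: exact at every resolution, change far below 2%
  expect_lt(tab$rel_change[2], 0.02)
  expect_equal(tab$current_A[1], 0.065 * 5e4 * 1e-4, tolerance = 1e-6)
})
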