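test_that("system enumeration reproduces the 20 x 2 x 7 taxonomy", {
  sys <- enumerate_systems()
  expect_equal(nrow(sys), 280)
  expect_equal(length(unique(sys$side_chain)), 20)
  expect_equal(length(unique(sys$backbone)), 2)
  expect_equal(length(unique(sys$complexation)), 7)
  expect_equal(sum(sys$complexation == "none"), 40)
  expect_equal(sum(sys$side_chain == "Gly"), 14)
  # deterministic lexicographic order
  expect_identical(sys, dplyr::arrange(
    sys, .data$side_chain, .data$protomer, .data$backbone, .data$complexation
  ))
  expect_false(anyDuplicated(sys$system) > 0)
})

test_that("protomer registry adds one variant per entry and combination", {
  sys <- enumerate_systems(include_protomers = TRUE)
  expect_equal(nrow(sys), 280 + 5 * 2 * 7)
  expect_setequal(
    unique(sys$side_chain[sys$protomer == "protonated"]),
    c("Arg", "Lys", "His", "Asp", "Glu")
  )
})

test_that("system ids round-trip through parsing", {
  sys <- enumerate_systems(include_protomers = TRUE)
  parsed <- parse_system_id(sys$system)
  expect_equal(parsed$side_chain, sys$side_chain)
  expect_equal(parsed$protomer, sys$protomer)
  expect_equal(parsed$backbone, sys$backbone)
  expect_equal(parsed$complexation, sys$complexation)
  expect_error(parse_system_id("not-an-id"), class = "pepc_error_system")
})
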