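test_that("codes parse from both text forms and round-trip canonically", {
  code <- parse_irma_code("1121-127-732-500")
  expect_equal(code$technical, "1121")
  expect_equal(code$directional, "127")
  expect_equal(code$anatomical, "732")
  expect_equal(code$biological, "500")

  code2 <- parse_irma_code("1121-410-620-625")
  expect_equal(code2$directional, "410")
  expect_equal(code2$biological, "625")

  # raw 13-character form parses to the same object
  expect_equal(parse_irma_code("1121127732500"), code)
  expect_equal(format(code), "1121-127-732-500")

  # parse -> format -> parse is the identity over random valid codes
  set.seed(42)
  alphabet <- c(0:9, letters)
  for (i in 1:50) {
    raw <- paste(sample(alphabet, 13, replace = TRUE), collapse = "")
    c1 <- parse_irma_code(raw)
    expect_equal(parse_irma_code(format(c1)), c1)
  }
})

test_that("malformed codes are rejected with the offending position", {
  expect_error(parse_irma_code("1121-127-732"), "13 characters")
  expect_error(parse_irma_code("1121/127-732-500x"), "17")
  expect_error(parse_irma_code("11211-27-732-500"), "positions 5, 9 and 13")
  expect_error(parse_irma_code("1121-127-73Z-500"), "illegal character 'Z' at axis position 10")
  expect_error(parse_irma_code("1121-127-7322500"), "position")
})

test_that("projection onto schemes extracts the right axis", {
  code <- parse_irma_code("1121-127-732-500")
  expect_equal(project_to_scheme(code, "T"), "1121")
  expect_equal(project_to_scheme(code, "D"), "127")
  expect_equal(project_to_scheme(code, "A"), "732")
  expect_equal(project_to_scheme(code, "IRMA"), "1121-127-732-500")
  expect_equal(project_to_scheme(parse_irma_code("1121-410-620-625"), "B"), "625")
  # accepts plain strings too
  expect_equal(project_to_scheme("1121-127-732-500", "A"), "732")

  # the IRMA label of a row determines all four axis labels
  set.seed(7)
  alphabet <- c(0:9, letters)
  for (i in 1:20) {
    raw <- paste(sample(alphabet, 13, replace = TRUE), collapse = "")
    full <- project_to_scheme(raw, "IRMA")
    expect_equal(paste0(project_to_scheme(full, "T"), project_to_scheme(full, "D"),
                        project_to_scheme(full, "A"), project_to_scheme(full, "B")),
                 gsub("-", "", full))
  }
})

test_that("class enumeration is sorted, distinct and scheme-consistent", {
  tab <- data.frame(image_id = c("a.png", "b.png"),
                    irma_code = c("1121-127-732-500", "1121-410-620-625"))
  expect_equal(enumerate_classes(tab, "T"), "1121")
  expect_equal(enumerate_classes(tab, "D"), c("127", "410"))
  expect_error(enumerate_classes(tab[0, ], "T"), "empty")

  # an axis never has more classes than the full code
  set.seed(11)
  alphabet <- c(0:9, letters)
  for (i in 1:10) {
    codes <- replicate(25, paste(sample(alphabet, 13, replace = TRUE), collapse = ""))
    tab <- data.frame(image_id = paste0(seq_along(codes), ".png"), irma_code = codes)
    n_full <- length(enumerate_classes(tab, "IRMA"))
    for (ax in c("T", "D", "A", "B"))
      expect_lte(length(enumerate_classes(tab, ax)), n_full)
  }

  # generator ground truth: vocab sizes are recovered
  tab <- micro_dataset()$labels
  expect_equal(length(enumerate_classes(tab, "T")), 2)
  expect_equal(length(enumerate_classes(tab, "D")), 2)
  expect_equal(length(enumerate_classes(tab, "B")), 1)
})

test_that("axis dictionaries decode known values and flag unknown ones", {
  a_dict <- system.file("extdata", "a-codes.tsv", package = "radannot")
  expect_equal(decode_axis_label("732", "A", a_dict),
               "Abdomen; Lower abdomen; Lower middle quadrant")
  t_dict <- system.file("extdata", "t-codes.tsv", package = "radannot")
  expect_equal(decode_axis_label("1124", "T", t_dict),
               "Xray; Plain Radiology; Analog; Low Beam Energy")
  expect_match(decode_axis_label("999", "A", a_dict), "unknown")
  expect_error(decode_axis_label("732", "A", "/nonexistent/file.tsv"), "not found")
})

test_that("label tables round-trip through CSV and reject duplicates", {
  tab <- data.frame(image_id = c("x.png", "y.png"),
                    irma_code = c("1121127732500", "1121-410-620-625"))
  f <- tempfile(fileext = ".csv")
  write_label_table(tab, f)
  back <- read_label_table(f)
  expect_equal(back$irma_code, c("1121-127-732-500", "1121-410-620-625"))
  expect_error(validate_label_table(
    data.frame(image_id = c("x.png", "x.png"),
               irma_code = c("1121-127-732-500", "1121-127-732-500"))),
    "duplicate")
  expect_error(validate_label_table(
    data.frame(image_id = "x.png", irma_code = "not-a-code")))
})
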