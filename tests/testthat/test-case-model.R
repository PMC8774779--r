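test_that("case_base construction validates schema and identifiers", {
  cb <- case_base(data.frame(stage = c("I", "II", "I"), age = c(40, 61, 55)),
                  y = c("benign", "malignant", "benign"))
  expect_s3_class(cb, "case_base")
  expect_equal(n_cases(cb), 3)
  expect_equal(cb$schema$kind, c("discrete", "continuous"))
  expect_setequal(cb$class_values, c("benign", "malignant"))
  expect_error(case_base(data.frame(a = 1:2), case_id = c("x", "x")),
               "duplicate case_id")
  expect_error(case_base(data.frame(a = 1:2), kinds = c(a = "fuzzy")),
               "unknown attribute kind")
})

test_that("validate_case reports violations and is empty iff valid", {
  cb <- case_base(data.frame(stage = c("I", "II"), age = c(40, 61)),
                  y = c("benign", "malignant"))
  expect_length(validate_case(get_case(cb, 1), cb), 0)
  bad_domain <- new_case(stage = "IV", age = 50)
  expect_length(validate_case(bad_domain, cb), 1)
  expect_match(validate_case(bad_domain, cb), "outside discrete domain")
  short <- list(case_id = NA, patient_id = NA, x = list(stage = "I"), y = NA)
  expect_match(validate_case(short, cb), "length")
})

test_that("normalize_continuous maps to [0,1], handles constants, is idempotent", {
  cb <- case_base(data.frame(a = c(0, 5, 10), b = c(7, 7, 7)))
  nr <- normalize_continuous(cb)
  expect_equal(nr$base$x$a, c(0, 0.5, 1))
  expect_equal(nr$base$x$b, c(0, 0, 0))
  twice <- normalize_continuous(nr$base)
  expect_equal(twice$base$x, nr$base$x)
  # target clipping above training max
  t <- apply_normalization(new_case(a = 12, b = 7), nr$map)
  expect_equal(t$x$a, 1)
  # all values within [0,1] on a generated base
  gen <- gen_case_base(case_gen_spec(n_cases = 50, seed = 7))
  gb <- normalize_continuous(gen$base)$base
  for (nm in gb$schema$name[gb$schema$kind == "continuous"]) {
    expect_true(all(gb$x[[nm]] >= 0 & gb$x[[nm]] <= 1))
  }
  expect_error(normalize_continuous(case_base(data.frame(a = NA_real_))),
               "no non-missing")
})

test_that("round-trip write/read is the identity in both formats", {
  gen <- gen_case_base(case_gen_spec(n_cases = 100, seed = 11))
  base <- gen$base
  base$x[3, "cont_inf_1"] <- NA   # a missing value must survive I/O
  base$x[5, "disc_inf_1"] <- NA
  base <- case_base(base$x, y = base$y, case_id = base$case_id,
                    patient_id = base$patient_id,
                    kinds = setNames(base$schema$kind, base$schema$name))
  for (fmt in c("csv", "jsonl")) {
    path <- tempfile(fileext = paste0(".", fmt))
    write_case_base(base, path, fmt)
    back <- read_case_base(path, fmt)
    expect_identical(back$case_id, base$case_id)
    expect_identical(back$y, base$y)
    expect_identical(back$schema, base$schema)
    for (nm in base$schema$name) {
      if (base$schema$kind[base$schema$name == nm] == "discrete") {
        expect_identical(back$x[[nm]], base$x[[nm]])
      } else {
        expect_equal(back$x[[nm]], base$x[[nm]], tolerance = 1e-12)
      }
    }
  }
})

test_that("empty and malformed files behave as contracted", {
  empty <- case_base(data.frame(a = numeric(0), b = character(0)),
                     kinds = c(a = "continuous", b = "discrete"))
  path <- tempfile(fileext = ".csv")
  write_case_base(empty, path)
  back <- read_case_base(path)
  expect_equal(n_cases(back), 0)
  expect_identical(back$schema, empty$schema)
  # duplicate case IDs fail on read
  lines <- readLines(path)
  bad <- c(lines, '"c1","p1","1","x","",""', '"c1","p1","2","y","",""')
  # construct a small duplicate-id file matching the dialect
  p2 <- tempfile(fileext = ".csv")
  writeLines(c("case_id,patient_id,a,class", "id,id,continuous,class",
               "c1,p1,1,pos", "c1,p1,2,neg"), p2)
  expect_error(read_case_base(p2), "duplicate case_id")
  p3 <- tempfile(fileext = ".csv")
  writeLines(c("case_id,patient_id,a,class", "id,id,continuous,class",
               "c1,p1,notanumber,pos"), p3)
  expect_error(read_case_base(p3), "row 1")
})

test_that("masking is irreversible on the masked fields and inert elsewhere", {
  gen <- gen_case_base(case_gen_spec(n_cases = 30, seed = 5))
  base <- gen$base
  masked <- mask_private_fields(base, "patient_id")
  expect_true(all(masked$patient_id == masked$patient_id[1]))
  expect_identical(masked$x, base$x)
  expect_identical(masked$y, base$y)
  expect_identical(masked$case_id, base$case_id)
  expect_equal(n_cases(masked), n_cases(base))
  expect_identical(mask_private_fields(base, character(0)), base)
  expect_error(mask_private_fields(base, "no_such_field"), "unknown field")
  # retrieval is unaffected by masking
  nb <- normalize_continuous(base)$base
  nm <- normalize_continuous(masked)$base
  w <- uniform_weights(nrow(base$schema))
  t <- get_case(nb, 1)
  expect_equal(retrieve_top_k(t, nb, w, k = 5)$case_id,
               retrieve_top_k(t, nm, w, k = 5)$case_id)
})
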