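# Shared fixtures: a hand-checkable two-study toy and the synthetic
# eight-trial log-OR table shipped in extdata.

toy_studies <- function() {
  tibble::tibble(label = c("A", "B"), effect = c(0, 1), se = c(0.5, 0.5))
}

fixture_path <- function() {
  system.file("extdata", "amantadine_synthetic.csv", package = "metapi")
}

# Full random-effects analysis of the synthetic fixture.
fixture_analysis <- function(pi_style = "rectangle") {
  studies <- read_study_table(fixture_path())
  pool <- pool_random(studies)
  pi <- pi_from_pool(pool)
  list(
    studies = studies, pool = pool, pi = pi,
    spec = build_forest_spec(studies, pool, pi, pi_style = pi_style)
  )
}

write_temp_csv <- function(df, envir = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = envir)
  readr::write_csv(df, path)
  path
}

random_studies <- function(k, se_range = c(0.1, 0.6)) {
  tibble::tibble(
    label = paste("S", seq_len(k)),
    effect = rnorm(k),
    se = runif(k, se_range[1], se_range[2])
  )
}
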