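# Shared fixtures built once per test run.
fx_db <- make_fixture_db(n_v = 6, n_d = 4, n_j = 3, seed = 11)
fx_scheme <- scoring_scheme()

fx_v <- function(i = 1) fx_db$sequence[fx_db$segment == "V"][i]
fx_j <- function(i = 1) fx_db$sequence[fx_db$segment == "J"][i]
fx_d <- function(i = 1) fx_db$sequence[fx_db$segment == "D"][i]

write_tmp_fasta <- function(records) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(unlist(purrr::imap(records, function(s, nm) c(paste0(">", nm),
                                                           s))), path)
  path
}
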