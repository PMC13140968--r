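# Hand-written miniature FAERS quarter for reader tests. Returns the
# directory; `demo_lines` etc. allow injecting malformed rows.
write_mini_quarter <- function(dir,
                               demo_lines = NULL, drug_lines = NULL,
                               reac_lines = NULL, ther_lines = NULL,
                               outc_lines = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  default <- list(
    DEMO = c("primaryid$caseid$fda_dt$event_dt$age$age_cod$sex$wt$wt_cod$occr_country$occp_cod",
             "101$10$20240110$20240105$63$YR$M$80$KG$US$MD",
             "201$20$20240215$202401$7$DEC$F$$$JP$"),
    DRUG = c("primaryid$drugname$role_cod",
             "101$KEYTRUDA$PS", "101$CISPLATIN$PS", "201$NIVOLUMAB$PS"),
    REAC = c("primaryid$pt", "101$Pyrexia", "101$Colitis", "201$Pyrexia"),
    THER = c("primaryid$dsg_drug_seq$start_dt", "101$1$20240101",
             "201$1$20240110"),
    OUTC = c("primaryid$outc_cod", "101$HO"))
  override <- list(DEMO = demo_lines, DRUG = drug_lines, REAC = reac_lines,
                   THER = ther_lines, OUTC = outc_lines)
  for (tab in names(default)) {
    lines <- override[[tab]] %||% default[[tab]]
    writeLines(lines, file.path(dir, paste0(tab, "24Q1.txt")))
  }
  dir
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small generator config for fast tests.
mini_config <- function(n_reports = 500L, seed = 99L, ...) {
  synthetic_config(n_reports = n_reports, seed = seed, ...)
}

null_associations <- data.frame(exposure = character(0), pt = character(0),
                                rr = numeric(0))

# Cached on-disk fixture shared across test files.
make_fixture <- function(n = 3000L, seed = 17L, ...) {
  d <- file.path(tempdir(), paste0("fix", seed, "_", n))
  if (!dir.exists(d)) generate_faers(mini_config(n, seed, ...), d)
  d
}
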