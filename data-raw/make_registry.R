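# Regenerates the shipped registry file from the programmatic builders.
# Run from the package root:  Rscript data-raw/make_registry.R
pkgload::load_all(".", quiet = TRUE)
reg <- build_default_registry()
stopifnot(nrow(reg) == 583L,
          sum(reg$category == "checkmol_base") == 200L,
          nrow(validate_registry(reg)$invalid_entries) == 0L)
write_registry(reg, file.path("inst", "extdata", "efg_registry.tsv"))
cat("wrote", nrow(reg), "entries to inst/extdata/efg_registry.tsv\n")
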