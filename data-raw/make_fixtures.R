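# Regenerates the packaged plain-text fixtures under inst/extdata from the
# package's deterministic synthetic generators. Run from the package root:
#   Rscript data-raw/make_fixtures.R
devtools::load_all(".", quiet = TRUE)

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
ref <- rcrs_synthetic()
write_reference_fasta(ref, "inst/extdata/rcrs_synthetic.fasta")
write_catalog(synthetic_catalog(ref), "inst/extdata/catalog_synthetic.tsv")
write_haplogroup_table(synthetic_haplogroup_tree(ref),
                       "inst/extdata/haplogroups_synthetic.tsv")
cat("fixtures written to inst/extdata\n")
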