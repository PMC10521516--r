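#!/usr/bin/env Rscript

# OPTIONAL: download the published Chenopodium Oxford Nanopore read
# libraries (the 50,000 longest reads per accession) from Zenodo record
# 6517222 and run the pipeline on one of them. These are multi-GB
# downloads; nothing in the package, its tests or the acceptance script
# requires them. Re-running the full published tabulation is
# parameter-sensitive and is provided here as a scripted experiment only.
#
# Usage: Rscript scripts/fetch_zenodo.R [accession] [outdir]
#   accession in: 429-3-acuminatum 433-9-iljinii 441-6-iljinii
#                 461-5-iljinii 177-pamiricum 830-3C-pamiricum
#                 328-10-suecicum

args <- commandArgs(trailingOnly = TRUE)
acc <- if (length(args) >= 1) args[1] else "429-3-acuminatum"
outdir <- if (length(args) >= 2) args[2] else "zenodo"

base <- "https://zenodo.org/record/6517222/files"
file <- sprintf("%s_ON_50000.fasta", acc)
url <- sprintf("%s/%s?download=1", base, file)
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
dest <- file.path(outdir, file)

if (!file.exists(dest)) {
  message("downloading ", url)
  utils::download.file(url, dest, mode = "wb")
}

library(teloscan)
summary <- run_pipeline(dest, out_dir = file.path(outdir, paste0(acc, "_out")),
                        top_n = 50000, library_id = acc)
print(summary)
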