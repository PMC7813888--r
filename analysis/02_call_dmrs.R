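#!/usr/bin/env Rscript

# Stage 2: call DMRs between VC and SC for the wild-type and the
# heterozygous-pool comparison, and score them against the planted
# truth. Reads the cytosine reports written by 01_simulate.R, so this
# stage exercises the same input path a reanalysis of deposited data
# would use.

suppressMessages(library(pollenDMR))

data_dir <- "results/data"
out <- "results"
truth <- read.table(file.path(data_dir, "truth_regions.tsv"),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
params <- dmr_params()  # 50-bp bins; 2/3/4 sites; 0.40/0.25/0.10; 400-bp merge

for (comp in c("wt", "het")) {
  vc <- parse_cytosine_report(
    file.path(data_dir, paste0("VC_", comp, ".cx_report.tsv")),
    cell_type = "VC")
  sc <- parse_cytosine_report(
    file.path(data_dir, paste0("SC_", comp, ".cx_report.tsv")),
    cell_type = "SC")
  dmrs <- dmr_table(call_dmrs(vc, sc, params))
  write_dmr_table(dmrs, file.path(out, paste0("dmrs_", comp, ".tsv")))
  write_dmr_bed(dmrs, file.path(out, paste0("dmrs_", comp, ".bed")))
  counts <- table(paste(dmrs$context, dmrs$direction))
  message(comp, " comparison: ",
          paste(names(counts), counts, collapse = ", "))
  hy <- dmrs[dmrs$context == "CG" & dmrs$direction == "hypo", ]
  sc_score <- score_recovery(hy, truth[truth$direction == "hypo", ],
                             min_reciprocal_overlap = 0.5)
  message(sprintf(
    "  CG-hypo recovery vs truth: precision %.3f, recall %.3f, footprint %d bp",
    sc_score$precision, sc_score$recall, sum(hy$end - hy$start)))
}
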