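#!/usr/bin/env Rscript
# Thin command-line driver over the venomest pipeline.
#
#   Rscript scripts/estpipe.R <command> [options]
#
# Commands:
#   simulate  --n-reads N --seed S --out DIR     generate a library + truth
#   run-all   --n-reads N --seed S --out DIR     full pipeline incl. mining
#   evaluate  --n-reads N --seed S --out DIR     run-all + truth evaluation
#
# All stage parameters use the package defaults; use the R functions
# directly for anything finer-grained.

suppressPackageStartupMessages(library(venomest))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1)
  stop("usage: estpipe.R <simulate|run-all|evaluate> [--n-reads N] ",
       "[--seed S] [--out DIR]")
cmd <- args[1]
get_arg <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
n_reads <- as.integer(get_arg("--n-reads", "1000"))
seed <- as.integer(get_arg("--seed", "1"))
out <- get_arg("--out", "estpipe_out")

cfg <- pipeline_config(generator = generator_config(n_reads = n_reads,
                                                    seed = seed))

if (cmd == "simulate") {
  world <- make_templates(cfg$generator)
  lib <- generate_library(cfg$generator, world)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write_est_set(lib$reads, file.path(out, "reads"))
  write_ground_truth(lib$truth, file.path(out, "ground_truth.json"))
  make_reference_collections(world, dir = out)
  cat(sprintf("simulated %d reads -> %s\n", length(lib$reads), out))
} else if (cmd %in% c("run-all", "evaluate")) {
  res <- run_pipeline(cfg, outdir = out, verbose = TRUE)
  print(res$abundance)
  if (cmd == "evaluate") {
    ev <- evaluate_against_truth(res, res$truth)
    for (n in setdiff(names(ev), "assembly"))
      cat(sprintf("%-16s sensitivity %.3f precision %.3f (%d called / %d planted)\n",
                  n, ev[[n]]$sensitivity, ev[[n]]$precision,
                  ev[[n]]$n_called, ev[[n]]$n_planted))
    cat(sprintf("mean consensus identity %.4f\n",
                ev$assembly$mean_consensus_identity))
  }
  cat(sprintf("reports written to %s\n", out))
} else {
  stop("unknown command: ", cmd)
}
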