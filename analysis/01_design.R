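#!/usr/bin/env Rscript
# Build the 2 x 3 Latin-square design: 14 occupations x 3 displays = 42
# experimental items rotated through the six (occupation x action) cells
# over six lists, plus 28 fillers, and a pseudo-randomized presentation
# order per list (first trial a filler, at most two experimental trials in
# a row).

suppressMessages({library(gazecluster); library(data.table)})
dir.create("results", showWarnings = FALSE)

item_set <- build_item_set(14, 3, 28)
lists <- latin_square_lists(item_set)
design <- design_table(lists, item_set, seed = 1L)

fwrite(design, "results/design_trials.tsv", sep = "\t")

cat("lists:", length(lists), "\n")
cat("experimental trials per list:", nrow(lists[[1]]), "\n")
cat("trials per condition cell:\n")
print(table(lists[[1]]$occupation_stereotype,
            lists[[1]]$action_stereotype))
inc <- rbindlist(lists)[, .N, by = .(item_id, cell)]
cat("Latin-square complete (every item in every cell exactly once):",
    all(inc$N == 1) && nrow(inc) == 42 * 6, "\n")
cat("wrote results/design_trials.tsv\n")
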