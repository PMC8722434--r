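#!/usr/bin/env Rscript
# Stage 4: subject identification — specificity and permanence.
#
# Specificity: stratified ten-fold CV within each session (how distinctive
# each subject's connectivity is on one day). Permanence: train on session A
# (day 1), test on sessions B-F in day order (how stable the fingerprint is
# over six months of simulated drift).

library(eegfp)

st <- readRDS("scratch/cohort.rds")
profile <- st$profile
feats <- readRDS("scratch/features.rds")

intra <- do.call(rbind, lapply(names(feats), function(kind) {
  fx <- feats[[kind]]
  data.frame(kind = kind,
             session_id = profile$sessions$session_id,
             accuracy = vapply(profile$sessions$session_id, function(sid) {
               as.numeric(intra_session_cv(
                 features_subset(fx, fx$session_id == sid),
                 k = profile$folds, cost = profile$cost, seed = profile$seed))
             }, numeric(1)))
}))
write.table(intra, "results/intra_session_accuracy.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

perm <- do.call(rbind, lapply(names(feats), function(kind) {
  res <- cross_session_eval(feats[[kind]], train_session = profile$train_session,
                            sessions = profile$sessions, cost = profile$cost,
                            seed = profile$seed)
  data.frame(kind = kind,
             session_id = names(res$per_session_accuracy),
             nominal_day = profile$sessions$nominal_day[
               match(names(res$per_session_accuracy),
                     profile$sessions$session_id)],
             accuracy = as.numeric(res$per_session_accuracy))
}))
write.table(perm, "results/permanence.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Intra-session accuracy (specificity):\n")
print(intra, row.names = FALSE)
cat("\nCross-session accuracy, trained on session A (permanence):\n")
print(perm, row.names = FALSE)
gc_perm <- perm[perm$kind == "GC", ]
cat("\nGC permanence:", round(gc_perm$accuracy[1], 3), "on day",
    gc_perm$nominal_day[1], "->", round(gc_perm$accuracy[nrow(gc_perm)], 3),
    "on day", gc_perm$nominal_day[nrow(gc_perm)], "\n")
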