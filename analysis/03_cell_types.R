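# Unit QC (spike-count floor, duplicate removal), burst index against the
# rate-matched Poisson ISI prediction, and unsupervised pyramidal vs
# interneuron classification by 2-means on (burst index, mean rate).

source("analysis/00_common.R")
sess <- load_or_simulate()
b <- sess$bundle

qc <- qc_units(b$units, b$duration)
cat(sprintf("QC: kept %d of %d units\n", length(qc$kept), length(b$units)))

profiles <- lapply(qc$kept, burst_index, duration = b$duration)
ct <- classify_cell_types(profiles, seed = SEED)
tab <- unit_table(ct$profiles)
write.csv(tab, file.path(RESULTS, "unit_table.csv"), row.names = FALSE)
print(table(tab$putative_type))

truth_type <- vapply(tab$unit_id, function(id) sess$truth$units[[id]]$type, "")
cat(sprintf("agreement with generator labels: %.0f%%\n",
            100 * mean(tab$putative_type == truth_type)))
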