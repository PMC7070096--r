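#!/usr/bin/env Rscript
# Single-column, single-stimulation ablation experiments.
#
# Builds 15 connectivity realizations of the 2000-neuron column, presents
# the triangular binary image once (51-70 ms, 1000 Hz), and scores the
# 160 ms readout against the input for: the intact column, chandelier-cell
# (LL-IN) ablations by layer, and the interneuron-class ablations
# (cross-layer CL, long-range LR, and CL+LR combined) in layer 2/3.
#
# Writes results/accuracy_single_stim.tsv and the input/output image pair
# of the last control trial as PBM files.

library(pfcmaint)

dir.create("results", showWarnings = FALSE)
cfg <- pfc_config()

message("Chandelier-cell ablation study (protocol a) ...")
rep_ll <- run_study(study_conditions("ll_single"), cfg)
message("Interneuron-class ablation study (protocol a) ...")
rep_cl <- run_study(study_conditions("classes_single"), cfg)

tab <- rbind(cbind(study = "ll_single", attr(rep_ll, "accuracy_table")),
             cbind(study = "classes_single", attr(rep_cl, "accuracy_table")))
write.table(tab, "results/accuracy_single_stim.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

# reconstructed output image of the last control trial
ctrl <- rep_ll$control
ras <- ctrl$last_raster
net_map <- 1:900  # ids of the L2/3 PCs in an intact column are 1..900
out <- decode_window(ras, net_map, ctrl$windows[[1]])
write_pbm(ctrl$pattern, "results/input_triangle.pbm")
write_pbm(out, "results/output_control_last_trial.pbm")

print(tab, digits = 4)
message("Accuracy of the intact column: ",
        sprintf("%.2f +/- %.2f %%", rep_ll$control$aggregate$mean,
                rep_ll$control$aggregate$sem))
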