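#!/usr/bin/env Rscript
# Fit the final RLS classifier on the extracted signature (lambda = median
# of the per-fold choices) and evaluate it on an independent test cohort
# drawn from the same population, extracting only the signature sub-matrix
# and centering it with the training means.

source("analysis/00_config.R")

data <- read_expression(file.path(data_dir, "matrix.tsv"),
                        file.path(data_dir, "labels.tsv"),
                        positive_class = "case",
                        negative_class = "control")
sig <- read_signature(file.path(results_dir, "signature.tsv"))
cv_report <- read.delim(file.path(results_dir, "cv_report.tsv"))

model <- final_model(data, sig, lambda = median(cv_report$lambda,
                                                na.rm = TRUE))
message(sprintf("final model: %d coefficients, lambda = %.4g",
                length(model$support), model$lambda))

# independent test cohort: same population, fresh seed
test_spec <- benchmark_spec()
test_spec$seed <- master_seed + 1
test_sim <- generate_dataset(test_spec)
cc <- evaluate_test(model, test_sim$data)
print(cc)

report <- data.frame(TP = cc$TP, FN = cc$FN, FP = cc$FP, TN = cc$TN,
                     n = cc$n, error = cc$error)
write.table(report, file.path(results_dir, "test_confusion.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("held-out test error: %d/%d = %.1f%%",
                cc$FP + cc$FN, cc$n, 100 * cc$error))
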