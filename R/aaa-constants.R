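# Shared constants (this file collates first).

BP_CLASSES <- c("normotensive", "prehypertensive", "hypertensive")

PAIRINGS <- c("norm_vs_pre", "norm_vs_hyp", "normpre_vs_hyp")

SELECTION_METHODS <- c("spearman", "relieff", "info_gain", "chi2", "mrmr", "gini")

CLASSIFIERS <- c("lda", "logistic", "cubic_svm", "weighted_knn")

# Native waveform level of each landmark: 0 = PPG, 1 = VPG, 2 = APG.
LANDMARK_LEVEL <- c(O = 0L, S = 0L, N = 0L, D = 0L, O2 = 0L,
                    w = 1L, x = 1L, y = 1L, z = 1L,
                    a = 2L, b = 2L, c = 2L, d = 2L, e = 2L)

META_COLS <- c("subject_id", "sbp", "dbp", "bp_class")
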