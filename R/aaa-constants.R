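# Shared constants: descriptor names, the canonical feature-table header,
# and the classifier panel. Defined first so every module can refer to them.

.octmf_feature_names <- c("Db", "Di", "Dc", "alpha_min", "alpha_max",
                          "alpha_center", "f_alpha_max", "spectrum_width",
                          "symmetric_shift")

.octmf_table_header <- c("ID", .octmf_feature_names, "class")

.octmf_model_names <- c("logistic_regression", "random_forest",
                        "decision_tree", "svm_poly", "gradient_boosting",
                        "xgboost_style_gbt", "lightgbm_style_gbt", "mlp")
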