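# data.table non-standard-evaluation column names
utils::globalVariables(c(
  ".N", ".SD", ".ord", ".row", ".time", "after_set", "age_band",
  "baseline_count", "baseline_count_band", "before_set", "bnf_chapter",
  "bnf_paragraph", "care_home", "code", "conservative_eligible", "continued",
  "count_before", "count_before_band", "daily_dose", "delta", "dose", "end",
  "end_date", "entry_date", "event", "event_date", "excluded_reason",
  "exit_date", "formulation", "fu_end", "grp", "issue_date", "issue_no",
  "last_collection_date", "max_count", "med_idx", "medicine", "model_term",
  "n_changed", "n_continued", "n_started", "n_stopped", "new_q",
  "patient_id", "person_level_townsend", "pos", "practice_id",
  "practice_townsend", "prior_year_review", "quantity", "region",
  "repeat_flag", "review_date", "rstart", "rend", "run_end", "source_repeat",
  "staff_role", "start", "start0", "start_date", "started", "step",
  "stopped", "consultation_type", "substance", "term", "time_days",
  "townsend", "townsend_quintile", "delta_true", "uts_date", "flagged", "p"))
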