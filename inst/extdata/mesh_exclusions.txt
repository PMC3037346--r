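Humans
Male
Female
Adult
Middle Aged
Aged
Aged, 80 and over
Adolescent
Child
Infant
Animals
Mice
Rats
Dogs
Prospective Studies
Retrospective Studies
Cohort Studies
Cross-Sectional Studies
Case-Control Studies
Double-Blind Method
Single-Blind Method
Randomized Controlled Trials as Topic
Clinical Trials as Topic
Follow-Up Studies
Longitudinal Studies
Time Factors
Treatment Outcome
Risk Factors
Severity of Illness Index
Questionnaires
Surveys and Questionnaires
Research Design
Reproducibility of Results
Sensitivity and Specificity
Predictive Value of Tests
Proportional Hazards Models
Survival Analysis
Multivariate Analysis
Data Interpretation, Statistical
Sample Size
Pilot Projects
Prevalence
Incidence
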