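PMID- 10001
DP  - 2006 Mar
TI  - Chronic heart failure management in primary care: a synthetic
      example record
AB  - A synthetic example abstract describing management of chronic heart
      failure and measurement of left ventricular ejection fraction.
MH  - *Heart Failure/drug therapy
MH  - Ventricular Dysfunction, Left
MH  - Humans
PT  - Journal Article
SRC - guideline-A

PMID- 10002
DP  - 2007 Jun
TI  - Dilated cardiomyopathy outcomes registry: a synthetic example record
AB  - A synthetic example abstract on cardiomyopathy cohorts.
MH  - Cardiomyopathy, Dilated/mortality
MH  - Humans
MH  - Male
PT  - Journal Article
SRC - guideline-B

PMID- 10003
DP  - 2005 Jan
TI  - Pulmonary congestion after admission: a synthetic example record
MH  - Pulmonary Edema
MH  - Humans
PT  - Journal Article
SRC - guideline-A
SRC - guideline-B
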