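# Organ-class keyword ruleset for target-lesion classification.
#
# Ordered: the first class (top to bottom) with a keyword contained in the
# lesion's normalized location text wins. Matching is case-insensitive
# substring matching on punctuation-stripped text. Edit freely; the reserved
# classes "Primary lesions" (assigned by lesion type) and "Unclassified
# lesions" (fallback) must not appear here.
#
# This list is a reconstruction of the organ keyword sets used for metastatic
# colorectal cancer lesion classification; the original keyword file is not
# public, so site experts should review and adapt it to their case report
# forms.
Liver:
  - liver
  - hepatic
  - hepat
Lung:
  - lung
  - pulmonary
  - pulmon
Lymph node:
  - lymph
  - node
  - nodal
  - adenopathy
Other respiratory organs:
  - pleura
  - pleural
  - mediastin
  - bronch
  - trachea
  - thoracic
Other digestive organs:
  - colon
  - colic
  - rectum
  - rectal
  - sigmoid
  - cecum
  - caecum
  - bowel
  - intestin
  - stomach
  - gastric
  - pancrea
  - spleen
  - splenic
  - periton
  - omentum
  - omental
  - mesenter
  - esophag
  - oesophag
  - anastomo
Other specified organs:
  - adrenal
  - kidney
  - renal
  - ovary
  - ovarian
  - uterus
  - uterine
  - bladder
  - bone
  - skin
  - subcutaneous
  - muscle
  - soft tissue
  - brain
  - cerebr
  - pelvi
  - abdominal wall
  - breast
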