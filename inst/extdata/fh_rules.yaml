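# Default family-history cancer-risk ruleset.
#
# A documented, configurable approximation of clinical testing criteria for
# hereditary breast/ovarian and colorectal cancer risk. A pedigree is
# stratified as increased risk when any rule fires. Fields per rule:
#   cancers        cancer terms counted by the rule
#   degrees        relative degrees counted (1 = parent/sibling/child,
#                  2 = grandparent/aunt-uncle; cousins are stored but
#                  excluded from rule counts by default)
#   min_count      minimum number of qualifying diagnoses
#   same_lineage   count maternal and paternal sides separately (siblings
#                  and children count toward both sides)
#   sex            optional sex constraint on the affected relative
#   age_max        optional age-at-diagnosis bound
#   age_inclusive  whether age_max is inclusive (<=) or strict (<)
#   age_min_count  how many of the counted diagnoses must meet age_max
#
# Unknown ages never satisfy an age bound on their own; for count-based
# rules (min_count >= 2) an unknown age may stand in for the age requirement,
# in which case the assessment is flagged ambiguous (the deterministic
# rendering of a case that a clinical team would resolve by consensus
# review).
options:
  include_third_degree: false
rules:
  - id: breast_early
    description: breast cancer diagnosed at 45 or younger in a 1st/2nd-degree relative
    cancers: [breast]
    degrees: [1, 2]
    min_count: 1
    age_max: 45
    age_inclusive: true
    age_min_count: 1
  - id: breast_two_same_lineage
    description: two or more breast cancers on the same side, at least one at 50 or younger
    cancers: [breast]
    degrees: [1, 2]
    same_lineage: true
    min_count: 2
    age_max: 50
    age_inclusive: true
    age_min_count: 1
  - id: ovarian_any_age
    description: ovarian cancer at any age in a 1st/2nd-degree relative
    cancers: [ovarian]
    degrees: [1, 2]
    min_count: 1
  - id: male_breast
    description: breast cancer in a male relative
    cancers: [breast]
    degrees: [1, 2]
    sex: M
    min_count: 1
  - id: breast_prostate_pancreatic_three
    description: three or more breast/prostate/pancreatic cancers on the same side, any age
    cancers: [breast, prostate, pancreatic]
    degrees: [1, 2]
    same_lineage: true
    min_count: 3
  - id: crc_endometrial_early
    description: colorectal or endometrial cancer before 50 in a 1st/2nd-degree relative
    cancers: [colorectal, endometrial]
    degrees: [1, 2]
    min_count: 1
    age_max: 50
    age_inclusive: false
    age_min_count: 1
  - id: lynch_two_same_lineage
    description: >-
      two Lynch-spectrum cancers on the same side with at least one diagnosed
      before 50 (unknown ages satisfy the age requirement only via the
      ambiguity relaxation)
    cancers: [colorectal, endometrial, ovarian, gastric, urothelial, bladder, small_bowel]
    degrees: [1, 2]
    same_lineage: true
    min_count: 2
    age_max: 50
    age_inclusive: false
    age_min_count: 1
  - id: lynch_three_same_lineage
    description: three or more Lynch-spectrum cancers on the same side, any age
    cancers: [colorectal, endometrial, ovarian, gastric, urothelial, bladder, small_bowel]
    degrees: [1, 2]
    same_lineage: true
    min_count: 3
  - id: unknown_type_two_early
    description: two or more cancers of unknown type before 50 on the same side
    cancers: [unknown_cancer]
    degrees: [1, 2]
    same_lineage: true
    min_count: 2
    age_max: 50
    age_inclusive: false
    age_min_count: 2
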