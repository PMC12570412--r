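factors:
- name: wealth_index
  domain: economic_stability
  levels:
  - quintile_1
  - quintile_2
  - quintile_3
  - quintile_4
  - quintile_5
  reference: quintile_1
  orientation: adverse_reference
- name: living_region
  domain: neighborhood_environment
  levels:
  - rural
  - urban
  reference: rural
  orientation: adverse_reference
- name: housing_type
  domain: neighborhood_environment
  levels:
  - other
  - single_house
  reference: other
  orientation: adverse_reference
- name: roof_material
  domain: neighborhood_environment
  levels:
  - light_or_mixed
  - strong
  reference: light_or_mixed
  orientation: adverse_reference
- name: wall_material
  domain: neighborhood_environment
  levels:
  - light_or_mixed
  - strong
  reference: light_or_mixed
  orientation: adverse_reference
- name: floor_material
  domain: neighborhood_environment
  levels:
  - other
  - cement
  - ceramic_tiles
  reference: other
  orientation: adverse_reference
- name: housing_tenure
  domain: neighborhood_environment
  levels:
  - rent
  - own
  reference: rent
  orientation: adverse_reference
- name: electricity
  domain: neighborhood_environment
  levels:
  - 'no'
  - 'yes'
  reference: 'no'
  orientation: adverse_reference
- name: education
  domain: education
  levels:
  - below_elementary
  - high_school
  - college_plus
  reference: below_elementary
  orientation: adverse_reference
- name: community_type
  domain: community_social_context
  levels:
  - rural
  - poblacion
  - city
  reference: rural
  orientation: adverse_reference
- name: marital_status
  domain: community_social_context
  levels:
  - unmarried_separated
  - widowed
  - married
  reference: unmarried_separated
  orientation: adverse_reference
- name: living_arrangement
  domain: community_social_context
  levels:
  - alone
  - with_others
  reference: alone
  orientation: adverse_reference
- name: num_friends_contact
  domain: community_social_context
  levels:
  - none
  - 1_2
  - 3_5
  - 6_plus
  reference: none
  orientation: adverse_reference
- name: num_friends_close
  domain: community_social_context
  levels:
  - none
  - 1_2
  - 3_5
  - 6_plus
  reference: none
  orientation: adverse_reference
- name: freq_social_activities
  domain: community_social_context
  levels:
  - never
  - a_few_times_a_year
  - monthly
  - weekly
  reference: never
  orientation: adverse_reference
- name: freq_seeing_friends
  domain: community_social_context
  levels:
  - never
  - yearly
  - monthly
  - weekly
  reference: never
  orientation: adverse_reference
- name: freq_hanging_out
  domain: community_social_context
  levels:
  - never
  - sometimes
  - often
  reference: never
  orientation: adverse_reference
- name: freq_gambling
  domain: community_social_context
  levels:
  - never
  - sometimes
  - often
  reference: never
  orientation: adverse_reference
- name: religious_services_outside
  domain: community_social_context
  levels:
  - 'no'
  - 'yes'
  reference: 'no'
  orientation: adverse_reference
- name: religious_activities_outside
  domain: community_social_context
  levels:
  - 'no'
  - 'yes'
  reference: 'no'
  orientation: adverse_reference
- name: religious_media
  domain: community_social_context
  levels:
  - 'no'
  - 'yes'
  reference: 'no'
  orientation: adverse_reference
- name: private_religious_activities
  domain: community_social_context
  levels:
  - 'no'
  - 'yes'
  reference: 'no'
  orientation: adverse_reference
- name: has_cellphone
  domain: community_social_context
  levels:
  - 'no'
  - 'yes'
  reference: 'no'
  orientation: adverse_reference
- name: has_internet
  domain: community_social_context
  levels:
  - 'no'
  - 'yes'
  reference: 'no'
  orientation: adverse_reference
- name: has_tablet_laptop
  domain: community_social_context
  levels:
  - 'no'
  - 'yes'
  reference: 'no'
  orientation: adverse_reference
- name: it_access
  domain: community_social_context
  levels:
  - 'no'
  - 'yes'
  reference: 'no'
  orientation: adverse_reference
- name: children_support
  domain: community_social_context
  levels:
  - 'no'
  - 'yes'
  reference: 'no'
  orientation: adverse_reference
- name: friends_support
  domain: community_social_context
  levels:
  - 'no'
  - 'yes'
  reference: 'no'
  orientation: adverse_reference
- name: health_insurance
  domain: healthcare_system
  levels:
  - 'no'
  - 'yes'
  reference: 'no'
  orientation: adverse_reference
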