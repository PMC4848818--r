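n_categories: 5
factors:
- name: psychological
  label: Psychological functioning
  marker: self_esteem
  items:
  - name: self_esteem
    label: Self-esteem
    reversed: no
  - name: body_image
    label: Body image
    reversed: no
  - name: negative_affects
    label: Negative affects
    reversed: yes
- name: physical
  label: Physical functioning
  marker: health_got_worse
  items:
  - name: feeling_tired
    label: Feeling tired
    reversed: yes
  - name: health_got_worse
    label: Health got worse
    reversed: yes
- name: self_efficacy
  label: Self-efficacy towards health services
  marker: confidence_contact
  items:
  - name: confidence_contact
    label: Confidence to know who to contact
    reversed: no
  - name: ability_information
    label: Ability to get information
    reversed: no
- name: lifestyle
  label: Lifestyle value
  marker: want_to_care
  items:
  - name: want_to_care
    label: Want to care
    reversed: no
  - name: enjoy_caring
    label: Enjoy caring
    reversed: no
  - name: caring_feels_good
    label: Caring makes one feel good
    reversed: no
- name: family_support
  label: Family support
  marker: difficulty_help
  items:
  - name: difficulty_help
    label: Difficulty getting help
    reversed: yes
  - name: feeling_abandoned
    label: Feeling abandoned
    reversed: yes
  - name: family_works_together
    label: Family works together
    reversed: no
- name: social_capital
  label: Social capital
  marker: personal_relationships
  items:
  - name: personal_relationships
    label: Personal relationships
    reversed: no
  - name: sexual_activity
    label: Sexual activity
    reversed: no
  - name: social_support
    label: Social support
    reversed: no
- name: material_security
  label: Material conditions / security
  marker: financial_resources
  items:
  - name: financial_resources
    label: Financial resources
    reversed: no
  - name: safety_security
    label: Freedom and physical safety and security
    reversed: no
- name: health_services
  label: Quality of information and healthcare services
  marker: help_received
  items:
  - name: help_received
    label: Help received
    reversed: no
  - name: availability_information
    label: Availability of information
    reversed: no
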