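# Observation rubrics for the five on-site preventive parameters.
# Every factor offers six options scored on the characteristic scale
# 1, 3, 5, 9, 15, 25 (left = lowest degree observed).  `direction` records
# whether the parameter multiplies (increasing) or divides (decreasing) the
# preventive-action assessment; the wording can be localised without
# touching code.
values: [1, 3, 5, 9, 15, 25]
tables:
  relative_risk:
    title: "Relative Risk - complexity of the unit of work observed"
    direction: increasing
    factors:
      graphics:
        [Without graphics, Verbal indication, Sketch, Technical detail,
         Formal plan, Technical equipment]
      setting_out:
        [Without reformulation, Reformulation by workman,
         Reformulation by supervisor, Reformulation by project manager,
         Technical equipment, Technical precision]
      workers:
        ["1", "2", "3", "4", "5", ">=6"]
      qualification:
        [Laborer, Foreman, Supervisor, Manager, Project Manager, Expert]
      auxiliary_systems_level:
        [Ground level, "<=1 m", "<=3 m", "<=5 m", "<=9 m", ">9 m"]
      tools_machinery:
        [None, Handheld tool, Hand-operated machine, Average vehicle,
         Heavy vehicle, HGV]
      material_weight:
        [Light, "<=9 kg", "<=50 kg", "<=150 kg", "<=500 kg", ">500 kg"]
      manageability:
        [1 person, 2 people, 3 people, With a machine, With a crane,
         Complex system]
  exposure:
    title: "Degree of Exposure to risk"
    direction: increasing
    factors:
      execution_intensity:
        [Never, Rare, Unusual, Occasional, Frequent, Continual]
      environment_intensity:
        [Never, Rare, Unusual, Occasional, Frequent, Continual]
  economic_capacity:
    title: "Economic Capacity - organizational procedure for work execution and safety"
    direction: decreasing
    factors:
      individual_organization:
        [Significant error, Highly disorganized, Little order, Order,
         Coordinated, Accurate]
      team_organization:
        [Errors, Disorganized, Little order, Order, Coordinated, Accurate]
      work_organization:
        [Errors, Disorganized, Little order, Order, Coordinated, Accurate]
      individual_protection:
        [None, 2 teams, 4 teams, 5 teams, 6 teams, ">6 teams"]
      collective_safeguards:
        [None, Very high risk, High risk, Medium risk, Low risk,
         100% free of risk]
  participative_interest:
    title: "Participative Interest in risk prevention"
    direction: decreasing
    factors:
      worker_information:
        [No information, Little information, Adequate information,
         A lot of information, Significant information, Demands information]
      individual_participation:
        [Does not participate, Barely participates, Participates a little,
         Participates a lot, Participates significantly, Demands safety]
      group_participation:
        [Do not participate, Barely participate, Participate a little,
         Participate a lot, Participate significantly, Demand safety]
      external_appearance:
        [No safety, Scarce safety, Little safety, Offers safety,
         Significant safety, Well maintained]
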