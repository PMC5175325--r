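# Item registry for the three pharmaceutical-regulation indices.
#
# Each index block lists its WHO survey items.  Fields per item:
#   id:     WHO question identifier (an "S" suffix marks a survey sub-item)
#   label:  short human-readable text
#   aspect: (private_market only) legal_framework | supply_chain | pharmacovigilance
#   derived: present only for composite items; declares the source columns
#     (years between inspections per market segment) the composite is built from.
#     The coding rule itself (regular / annual inspection variants) is implemented
#     by buildInspectionsComposite().
infrastructure:
  items:
    - id: "3.01.04"
      label: "National medicines policy official document exists"
    - id: "3.01.12"
      label: "Pharmaceutical policy implementation regularly monitored/assessed"
    - id: "3.01.14"
      label: "Policy to manage and sanction conflicts of interest"
    - id: "3.01.16"
      label: "Whistle-blowing mechanism for the pharmaceutical sector"
    - id: "5.01.01"
      label: "Legal provisions establish powers and responsibilities of the MRA"
    - id: "5.01.02"
      label: "An MRA exists"
    - id: "5.01.04.02"
      label: "MRA is a semi-autonomous agency"
    - id: "5.01.10"
      label: "Assessment of the regulatory system conducted in the last five years"
    - id: "5.01.11"
      label: "MRA gets funds from the regular government budget"
    - id: "5.01.15"
      label: "MRA uses a computerized information management system"
    - id: "5.02.15S"
      label: "Declaration of potential conflicts of interest by registration experts"
    - id: "5.05.03"
      label: "GMP requirements published by the government"
    - id: "5.05.07"
      label: "National Good Distribution Practice requirements published"
    - id: "5.05.11"
      label: "National Good Pharmacy Practice guidelines published"
private_market:
  items:
    - id: "5.02.08"
      label: "Medicines registration always includes the INN"
      aspect: legal_framework
    - id: "5.02.12S"
      label: "Publication of SPCs of registered medicines required"
      aspect: legal_framework
    - id: "5.05.01"
      label: "Manufacturers required to be licensed"
      aspect: legal_framework
    - id: "5.05.02"
      label: "Domestic and international manufacturers must comply with GMP"
      aspect: legal_framework
    - id: "5.05.05"
      label: "Wholesalers and distributors must be licensed"
      aspect: legal_framework
    - id: "5.05.06"
      label: "Wholesalers and distributors must comply with GDP"
      aspect: legal_framework
    - id: "5.05.08"
      label: "Pharmacists required to be registered"
      aspect: legal_framework
    - id: "5.05.09"
      label: "Private pharmacies required to be licensed"
      aspect: legal_framework
    - id: "5.07.01"
      label: "Legal provisions control promotion/advertising of prescription medicines"
      aspect: legal_framework
    - id: "5.03.05.01"
      label: "Local manufacturers inspected for GMP compliance"
      aspect: supply_chain
    - id: "5.03.05.02"
      label: "Private wholesalers inspected"
      aspect: supply_chain
    - id: "5.03.05.03"
      label: "Retail distributors inspected"
      aspect: supply_chain
    - id: "5.03.05.05"
      label: "Pharmacies and dispensing points of health facilities inspected"
      aspect: supply_chain
    - id: "inspections"
      label: "Regularity of inspections"
      aspect: supply_chain
      derived:
        sources:
          - "insp.freq.manufacturers"
          - "insp.freq.retail"
          - "insp.freq.dispensing"
    - id: "5.04.02"
      label: "Sampling of imported products for testing allowed"
      aspect: supply_chain
    - id: "5.04.03"
      label: "Importation only through authorized ports of entry"
      aspect: supply_chain
    - id: "5.04.04"
      label: "Inspection of imported pharmaceutical products at ports of entry"
      aspect: supply_chain
    - id: "5.05.04"
      label: "Importers required to be licensed"
      aspect: supply_chain
    - id: "5.10.01"
      label: "Pharmacovigilance part of the MRA mandate"
      aspect: pharmacovigilance
    - id: "5.10.02"
      label: "Marketing authorization holder must monitor safety and report to the MRA"
      aspect: pharmacovigilance
    - id: "5.10.03"
      label: "Legal provisions on monitoring Adverse Drug Reactions"
      aspect: pharmacovigilance
    - id: "5.10.05"
      label: "Official standardized form for reporting ADRs used"
      aspect: pharmacovigilance
    - id: "5.10.06"
      label: "National ADR database exists"
      aspect: pharmacovigilance
    - id: "5.10.10"
      label: "National ADR/pharmacovigilance advisory committee exists"
      aspect: pharmacovigilance
    - id: "5.10.16S"
      label: "ADR database is computerized"
      aspect: pharmacovigilance
    - id: "5.10.22S"
      label: "Training courses in pharmacovigilance exist"
      aspect: pharmacovigilance
public_quality:
  items:
    - id: "5.03.05.04"
      label: "Public pharmacies and stores inspected"
    - id: "5.03.05.05"
      label: "Pharmacies and dispensing points of health facilities inspected"
    - id: "5.05.08"
      label: "Pharmacists required to be registered"
    - id: "5.05.10"
      label: "Public pharmacies required to be licensed"
    - id: "5.06.04.01"
      label: "Quality monitoring in the public sector (routine sampling)"
    - id: "5.06.04.06"
      label: "Testing of public program products prior to acceptance/distribution"
    - id: "7.01.03"
      label: "Public sector requests for tender publicly available"
    - id: "7.01.04"
      label: "Public sector tender awards publicly available"
    - id: "7.01.05"
      label: "System to prequalify suppliers"
    - id: "7.01.07S"
      label: "Written public sector procurement policy"
    - id: "7.01.10S"
      label: "Process exists to ensure the quality of products procured"
    - id: "7.01.11S"
      label: "List of samples tested during procurement and quality-testing results available"
    - id: "7.01.12.01S"
      label: "Tenders are nationally competitive"
    - id: "7.01.12.02S"
      label: "Tenders are internationally competitive"
    - id: "7.02.03"
      label: "National guidelines on Good Distribution Practices"
    - id: "7.10.10.01S"
      label: "Quality assurance includes prequalification of products and suppliers"
    - id: "7.10.10.02S"
      label: "Explicit criteria and procedures for prequalification of suppliers"
    - id: "7.10.10.03S"
      label: "List of prequalified suppliers and products publicly available"
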