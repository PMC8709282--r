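<?xml version="1.0" encoding="UTF-8"?>
<!-- Synthetic, hand-written miniature of the DrugBank full-database export
     schema (5.x). Contains no real DrugBank content; drug names and gene
     names are invented for parser testing. -->
<drugbank xmlns="http://www.drugbank.ca" version="5.1-synthetic">
  <drug type="small molecule">
    <drugbank-id primary="true">SYNDB0001</drugbank-id>
    <drugbank-id>SYNDB0001-ALT</drugbank-id>
    <name>Examplomab</name>
    <groups>
      <group>approved</group>
    </groups>
    <atc-codes>
      <atc-code code="L04AC06"/>
    </atc-codes>
    <targets>
      <target>
        <name>Example receptor alpha</name>
        <actions>
          <action>antagonist</action>
        </actions>
        <polypeptide id="SYNP1" source="Swiss-Prot">
          <gene-name>EXR1</gene-name>
        </polypeptide>
      </target>
    </targets>
    <enzymes>
      <enzyme>
        <name>Example oxidase</name>
        <actions>
          <action>substrate</action>
        </actions>
        <polypeptide id="SYNP2" source="Swiss-Prot">
          <gene-name>EOX1</gene-name>
        </polypeptide>
      </enzyme>
    </enzymes>
  </drug>
  <drug type="small molecule">
    <drugbank-id primary="true">SYNDB0002</drugbank-id>
    <name>Testasterone</name>
    <groups>
      <group>approved</group>
      <group>investigational</group>
    </groups>
    <atc-codes>
      <atc-code code="A11HA06"/>
      <atc-code code="N02BA01"/>
    </atc-codes>
    <targets>
      <target>
        <name>Example receptor alpha</name>
        <actions>
          <action>agonist</action>
          <action>inhibitor</action>
        </actions>
        <polypeptide id="SYNP1" source="Swiss-Prot">
          <gene-name>EXR1</gene-name>
        </polypeptide>
      </target>
      <target>
        <name>Orphan protein without gene name</name>
        <polypeptide id="SYNP3" source="Swiss-Prot">
          <gene-name></gene-name>
        </polypeptide>
      </target>
    </targets>
  </drug>
  <drug type="biotech">
    <drugbank-id primary="true">SYNDB0003</drugbank-id>
    <name>Investigatol</name>
    <groups>
      <group>investigational</group>
    </groups>
    <targets>
      <target>
        <name>Example channel</name>
        <actions>
          <action>blocker</action>
        </actions>
        <polypeptide id="SYNP4" source="Swiss-Prot">
          <gene-name>EXC1</gene-name>
        </polypeptide>
      </target>
    </targets>
  </drug>
</drugbank>
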