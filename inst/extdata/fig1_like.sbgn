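<?xml version="1.0" encoding="UTF-8"?>
<sbgn xmlns="http://sbgn.org/libsbgn/0.2">
  <map language="process description" id="fig1_like">
    <glyph class="compartment" id="cp_nuc">
      <label text="nucleoplasm"/>
      <bbox x="0" y="0" w="900" h="600"/>
    </glyph>
    <glyph class="complex" id="cx_mrn" compartmentRef="cp_nuc">
      <label text="MRN"/>
      <bbox x="40" y="60" w="120" h="80"/>
      <glyph class="macromolecule" id="m_mre11">
        <label text="MRE11"/>
        <bbox x="50" y="70" w="80" h="40"/>
      </glyph>
      <glyph class="macromolecule" id="m_nbn_c">
        <label text="NBN"/>
        <bbox x="50" y="130" w="80" h="40"/>
      </glyph>
      <glyph class="macromolecule" id="m_rad50">
        <label text="RAD50"/>
        <bbox x="50" y="100" w="80" h="40"/>
      </glyph>
    </glyph>
    <glyph class="macromolecule" id="ep_atm" compartmentRef="cp_nuc">
      <label text="ATM"/>
      <bbox x="200" y="60" w="80" h="40"/>
    </glyph>
    <glyph class="macromolecule" id="ep_atm_p" compartmentRef="cp_nuc">
      <label text="ATM-P"/>
      <bbox x="200" y="60" w="80" h="40"/>
    </glyph>
    <glyph class="macromolecule" id="ep_nbn" compartmentRef="cp_nuc">
      <label text="NBN"/>
      <bbox x="200" y="60" w="80" h="40"/>
    </glyph>
    <glyph class="macromolecule" id="ep_nbn_p" compartmentRef="cp_nuc">
      <label text="NBN-P"/>
      <bbox x="200" y="60" w="80" h="40"/>
    </glyph>
    <glyph class="macromolecule" id="ep_ra" compartmentRef="cp_nuc">
      <label text="repairA"/>
      <bbox x="200" y="60" w="80" h="40"/>
    </glyph>
    <glyph class="macromolecule" id="ep_ra_p" compartmentRef="cp_nuc">
      <label text="repairA-P"/>
      <bbox x="200" y="60" w="80" h="40"/>
    </glyph>
    <glyph class="macromolecule" id="ep_rb" compartmentRef="cp_nuc">
      <label text="repairB"/>
      <bbox x="200" y="60" w="80" h="40"/>
    </glyph>
    <glyph class="macromolecule" id="ep_rb_p" compartmentRef="cp_nuc">
      <label text="repairB-P"/>
      <bbox x="200" y="60" w="80" h="40"/>
    </glyph>
    <glyph class="process" id="pr1" compartmentRef="cp_nuc">
      <bbox x="400" y="60" w="20" h="20"/>
    </glyph>
    <glyph class="process" id="pr2" compartmentRef="cp_nuc">
      <bbox x="400" y="60" w="20" h="20"/>
    </glyph>
    <glyph class="process" id="pr3" compartmentRef="cp_nuc">
      <bbox x="400" y="60" w="20" h="20"/>
    </glyph>
    <glyph class="process" id="pr4" compartmentRef="cp_nuc">
      <bbox x="400" y="60" w="20" h="20"/>
    </glyph>
    <arc class="consumption" id="arc1" source="ep_nbn" target="pr1"/>
    <arc class="consumption" id="arc10" source="ep_rb" target="pr4"/>
    <arc class="production" id="arc11" source="pr4" target="ep_rb_p"/>
    <arc class="catalysis" id="arc12" source="ep_nbn" target="pr4"/>
    <arc class="production" id="arc2" source="pr1" target="ep_nbn_p"/>
    <arc class="catalysis" id="arc3" source="ep_atm" target="pr1"/>
    <arc class="consumption" id="arc4" source="ep_atm" target="pr2"/>
    <arc class="production" id="arc5" source="pr2" target="ep_atm_p"/>
    <arc class="stimulation" id="arc6" source="cx_mrn" target="pr2"/>
    <arc class="consumption" id="arc7" source="ep_ra" target="pr3"/>
    <arc class="production" id="arc8" source="pr3" target="ep_ra_p"/>
    <arc class="catalysis" id="arc9" source="ep_nbn_p" target="pr3"/>
  </map>
</sbgn>
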